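#' Representational similarity (dissimilarity) matrix
#'
#' @param mat Square symmetric matrix of dissimilarities with zero
#'   diagonal (NA entries allowed only when flagged degenerate).
#' @param agent Agent tag.
#' @param level `"condition"` or `"picturewise"`.
#' @return An `rsm` object.
#' @export
rsm <- function(mat, agent = "", level = "condition") {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stopf("rsm: matrix not square")
  if (max(abs(mat - t(mat)), na.rm = TRUE) > 1e-10) stopf("rsm: matrix not symmetric")
  if (any(abs(diag(mat)) > 1e-12, na.rm = TRUE)) stopf("rsm: nonzero diagonal")
  structure(mat, class = c("rsm", "matrix"), agent = agent, level = level)
}

#' @export
print.rsm <- function(x, ...) {
  cat(sprintf("<rsm> %dx%d [%s, %s]\n", nrow(x), ncol(x),
              attr(x, "agent"), attr(x, "level")))
  print(round(unclass(x)[seq_len(min(8L, nrow(x))), seq_len(min(8L, ncol(x)))], 3))
  invisible(x)
}

upper_tri_vec <- function(m) unclass(m)[upper.tri(m)]

# |S(i - j) - 0.5| folded into a numerosities x numerosities block; the
# reported-rate symmetry S(d) + S(-d) = 1 makes it symmetric, and the
# diagonal (d = 0) is set to 0 in dissimilarity form.
curve_block <- function(curve, levels = 1:7) {
  d <- outer(levels, levels, `-`)
  M <- matrix(abs(curve_rate_at(curve, as.vector(d)) - 0.5), length(levels))
  M <- (M + t(M)) / 2          # guards against sampling asymmetry at +/- d
  diag(M) <- 0
  M
}

#' Condition-level RSM from superior / inferior psychometric curves
#'
#' Fills the two S-curves into one dissimilarity matrix per agent:
#' within each condition, the discriminability `|S(i - j) - 0.5|` of
#' numerosities i and j forms a 7 x 7 block, and the two blocks are
#' assembled block-diagonally (14 x 14). The alternative reading --
#' comparing the two curves directly as one concatenated vector -- is
#' available as `method = "concat"` and yields an `rsa_vector` that
#' [compare_rsms()] accepts alongside RSMs.
#'
#' @param curve_superior,curve_inferior [psych_curve()]s over the full
#'   distance range.
#' @param agent Agent tag.
#' @param method `"blockdiag"` (default) or `"concat"`.
#' @param levels Numerosity levels (default 1..7).
#' @return An [rsm()] (or an `rsa_vector` for `method = "concat"`).
#' @export
rsm_from_curves <- function(curve_superior, curve_inferior, agent = "",
                            method = c("blockdiag", "concat"), levels = 1:7) {
  method <- match.arg(method)
  if (method == "concat") {
    v <- c(curve_superior$rate, curve_inferior$rate)
    return(structure(list(values = v, agent = agent), class = "rsa_vector"))
  }
  bs <- curve_block(curve_superior, levels)
  bi <- curve_block(curve_inferior, levels)
  k <- length(levels)
  M <- matrix(0, 2L * k, 2L * k)
  M[seq_len(k), seq_len(k)] <- bs
  M[k + seq_len(k), k + seq_len(k)] <- bi
  out <- rsm(M, agent = agent, level = "condition")
  # comparisons use the within-condition dissimilarities only; the
  # between-condition cells are structural zeros, not measurements
  attr(out, "blocks") <- list(seq_len(k), k + seq_len(k))
  out
}

#' Picture-wise RSM from pairwise comparison outcomes
#'
#' Picture `i`'s response profile is its win-rate vector against every
#' other picture; the dissimilarity of pictures i and j is
#' `1 - Pearson(profile_i, profile_j)` computed over the remaining
#' pictures (entries i and j excluded from both profiles). Pictures with
#' a constant profile have undefined correlations; they are flagged in
#' attribute `"degenerate"` and their entries set to NA.
#'
#' @param outcomes Square win-rate matrix (`outcomes[i, j]` = rate at
#'   which picture i was reported greater than picture j).
#' @param agent Agent tag.
#' @return An [rsm()] at the picture-wise level.
#' @export
rsm_picturewise <- function(outcomes, agent = "") {
  outcomes <- as.matrix(outcomes)
  n <- nrow(outcomes)
  if (n != ncol(outcomes)) stopf("rsm_picturewise: outcome table not square")
  M <- matrix(0, n, n)
  degen <- logical(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    keep <- setdiff(seq_len(n), c(i, j))
    pi <- outcomes[i, keep]; pj <- outcomes[j, keep]
    if (stats::sd(pi) == 0 || stats::sd(pj) == 0) {
      M[i, j] <- M[j, i] <- NA_real_
      degen[i] <- degen[i] || stats::sd(pi) == 0
      degen[j] <- degen[j] || stats::sd(pj) == 0
    } else {
      M[i, j] <- M[j, i] <- 1 - stats::cor(pi, pj)
    }
  }
  out <- rsm(M, agent = agent, level = "picturewise")
  attr(out, "degenerate") <- which(degen)
  out
}

as_rsa_vec <- function(x) {
  if (inherits(x, "rsa_vector")) return(x$values)
  blocks <- attr(x, "blocks", exact = TRUE)
  if (is.null(blocks)) return(upper_tri_vec(x))
  unlist(lapply(blocks, function(b) upper_tri_vec(unclass(x)[b, b])))
}

#' Compare candidate RSMs against a reference set
#'
#' For each candidate, the Spearman correlation between its upper
#' triangle and each reference's upper triangle is computed; a
#' one-sided Wilcoxon signed-rank test across the references asks
#' whether the correlations exceed zero. Candidates are also compared
#' pairwise (paired signed-rank on the per-reference correlations). All
#' p-values are false-discovery-rate adjusted together.
#'
#' @param references List of >= `min_refs` [rsm()]s (one per
#'   participant or per repeated network run).
#' @param candidates Named list of [rsm()]s (or `rsa_vector`s).
#' @param min_refs Minimum reference-set size (default 12).
#' @param alpha Significance level used for the `significant` flag.
#' @return List with `candidate_tests` (ranked data frame),
#'   `pairwise` (data frame) and `correlations` (candidate x reference
#'   matrix).
#' @export
compare_rsms <- function(references, candidates, min_refs = 12L, alpha = 0.05) {
  if (length(references) < min_refs)
    stopf("compare_rsms: %d reference RSMs supplied, need >= %d",
          length(references), min_refs)
  if (is.null(names(candidates)))
    names(candidates) <- sprintf("candidate%d", seq_along(candidates))
  ref_vecs <- lapply(references, as_rsa_vec)
  len <- unique(vapply(ref_vecs, length, integer(1)))
  if (length(len) != 1L) stopf("compare_rsms: reference shape mismatch")
  cor_mat <- matrix(NA_real_, length(candidates), length(references),
                    dimnames = list(names(candidates), NULL))
  for (k in seq_along(candidates)) {
    cv <- as_rsa_vec(candidates[[k]])
    if (length(cv) != len) stopf("compare_rsms: candidate '%s' shape mismatch",
                                 names(candidates)[k])
    cor_mat[k, ] <- vapply(ref_vecs, function(rv) {
      ok <- is.finite(cv) & is.finite(rv)
      stats::cor(cv[ok], rv[ok], method = "spearman")
    }, numeric(1))
  }
  ref_p <- vapply(seq_along(candidates), function(k)
    suppressWarnings(stats::wilcox.test(cor_mat[k, ], mu = 0,
                                        alternative = "greater")$p.value),
    numeric(1))
  pair <- NULL
  if (length(candidates) > 1L) {
    cmb <- utils::combn(length(candidates), 2L)
    pair <- data.frame(a = names(candidates)[cmb[1L, ]],
                       b = names(candidates)[cmb[2L, ]],
                       p = apply(cmb, 2L, function(ij)
                         suppressWarnings(stats::wilcox.test(
                           cor_mat[ij[1L], ], cor_mat[ij[2L], ],
                           paired = TRUE)$p.value)))
  }
  all_p <- c(ref_p, pair$p)
  adj <- stats::p.adjust(all_p, method = "fdr")
  cand <- data.frame(candidate = names(candidates),
                     mean_r = rowMeans(cor_mat),
                     median_r = apply(cor_mat, 1L, stats::median),
                     p = ref_p,
                     p_fdr = adj[seq_along(ref_p)])
  cand$significant <- cand$p_fdr < alpha
  cand <- cand[order(-cand$mean_r), ]
  rownames(cand) <- NULL
  if (!is.null(pair)) pair$p_fdr <- adj[-seq_along(ref_p)]
  list(candidate_tests = cand, pairwise = pair, correlations = cor_mat)
}

#' Apply a common item permutation to an RSM
#'
#' Used for shuffled-control candidates and permutation nulls. For
#' condition-level RSMs built from curves (which carry per-condition
#' blocks), one permutation of the numerosities is drawn and applied
#' within every block, preserving the block structure.
#'
#' @param x An [rsm()].
#' @param perm Permutation of the item indices (default: random, seeded).
#' @param seed RNG seed when `perm` is missing.
#' @param scope `"items"` permutes item labels (rows/columns; within
#'   blocks for condition-level RSMs, which preserves the condition
#'   contrast); `"entries"` permutes the comparison entries themselves,
#'   destroying all structure including the condition contrast -- the
#'   fully destructive null.
#' @return The permuted [rsm()] (an `rsa_vector` for
#'   `scope = "entries"`).
#' @export
shuffle_rsm <- function(x, perm = NULL, seed = 1L, scope = c("items", "entries")) {
  scope <- match.arg(scope)
  if (scope == "entries") {
    v <- as_rsa_vec(x)
    if (is.null(perm)) perm <- with_seed(seed, sample.int(length(v)))
    return(structure(list(values = v[perm],
                          agent = paste0(attr(x, "agent"), "_shuffled")),
                     class = "rsa_vector"))
  }
  blocks <- attr(x, "blocks", exact = TRUE)
  n <- nrow(x)
  if (is.null(blocks)) {
    if (is.null(perm)) perm <- with_seed(seed, sample.int(n))
    return(rsm(unclass(x)[perm, perm],
               agent = paste0(attr(x, "agent"), "_shuffled"),
               level = attr(x, "level")))
  }
  k <- length(blocks[[1L]])
  if (is.null(perm)) perm <- with_seed(seed, sample.int(k))
  full <- unlist(lapply(blocks, function(b) b[perm]))
  out <- rsm(unclass(x)[full, full],
             agent = paste0(attr(x, "agent"), "_shuffled"),
             level = attr(x, "level"))
  attr(out, "blocks") <- blocks
  out
}
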