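#' Per-subject change in a feature between timepoints
#'
#' @param t0,t1 Named numeric vectors of a feature per subject; subjects are
#'   matched by name.
#' @param mode `"absolute"` (`t1 - t0`) or `"percent"`
#'   (`100 * (t1 - t0) / t0`; subjects with a zero baseline are excluded
#'   and listed).
#' @return List with `delta` (named vector over the retained subjects) and
#'   `excluded` (tibble of subject and reason).
#' @export
delta_feature <- function(t0, t1, mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  shared <- intersect(names(t0), names(t1))
  if (length(shared) == 0L) stop("no shared subjects", call. = FALSE)
  a <- t0[shared]; b <- t1[shared]
  excluded <- tibble::tibble(subject_id = character(), reason = character())
  if (mode == "absolute") {
    delta <- b - a
  } else {
    zero <- a == 0
    if (any(zero)) {
      excluded <- tibble::tibble(subject_id = shared[zero],
                                 reason = "zero baseline")
      a <- a[!zero]; b <- b[!zero]
    }
    delta <- 100 * (b - a) / a
  }
  list(delta = delta, excluded = excluded)
}

#' Rank genes by Spearman association with a sample-level feature
#'
#' For every gene, Spearman's rank correlation (average ranks on ties)
#' between its expression across samples and the feature, with a two-sided
#' p-value and Benjamini-Hochberg q-value. Genes are then split by the sign
#' of the correlation into a positively associated `top_list` and a
#' negatively associated `bottom_list`, each ranked by strength of
#' association and truncated to `n_top` (default 500, the conventional
#' list size for feature-association browsing); the lists always truncate
#' at the sign boundary, so fewer than `n_top` genes may qualify.
#'
#' p-values use the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` for n > 9 samples; for the tiny
#' cohorts typical of PDX arms (n <= 9) the exact permutation null of
#' Spearman's statistic is used instead (full enumeration, valid in the
#' absence of ties; tied genes at small n fall back to the
#' t-approximation).
#'
#' @param expr An [expression_matrix()].
#' @param feature Named numeric vector, one value per sample; matched to
#'   `expr` columns by name. Must be non-constant with >= 3 shared samples.
#' @param n_top Maximum list length (default 500).
#' @return List of class `association_result`: `table` (tibble with
#'   `gene`, `rho`, `p_value`, `q_value`, `n`; constant genes get `NaN`
#'   rho and are excluded from the lists), `top_list`, `bottom_list`,
#'   `n_samples`, plus `feature_name`/`cohort`/`timepoint_mode` metadata.
#' @param feature_name,timepoint_mode Metadata strings echoed in the result.
#' @export
spearman_associate <- function(expr, feature, n_top = 500L,
                               feature_name = "feature",
                               timepoint_mode = "T0") {
  stopifnot(inherits(expr, "expression_matrix"))
  shared <- intersect(colnames(expr), names(feature))
  n <- length(shared)
  if (n < 3L) stop("need >= 3 samples shared with the feature", call. = FALSE)
  f <- feature[shared]
  if (length(unique(f)) == 1L) {
    stop("feature is constant across samples", call. = FALSE)
  }
  x <- unclass(expr)[, shared, drop = FALSE]

  rf <- rank(f)                       # average ranks on ties
  rg <- t(apply(x, 1L, rank))
  rho <- ranked_pearson(rg, rf)

  p <- rep(NA_real_, length(rho))
  ok <- is.finite(rho)
  if (n > 9L) {
    p[ok] <- spearman_p_t(rho[ok], n)
  } else {
    feature_tied <- anyDuplicated(f) > 0L
    gene_tied <- apply(x, 1L, anyDuplicated) > 0L
    exact_ok <- ok & !feature_tied & !gene_tied
    p[exact_ok] <- spearman_p_exact(rho[exact_ok], n)
    approx_ok <- ok & !exact_ok
    p[approx_ok] <- spearman_p_t(rho[approx_ok], n)
  }
  q <- rep(NA_real_, length(rho))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")

  tab <- tibble::tibble(gene = rownames(x), rho = rho, p_value = p,
                        q_value = q, n = n)

  rank_side <- function(sign_pos) {
    side <- tab[ok & if (sign_pos) tab$rho > 0 else tab$rho < 0, ,
                drop = FALSE]
    ord <- order(-abs(side$rho), side$p_value, side$gene, method = "radix")
    utils::head(side$gene[ord], n_top)
  }

  structure(
    list(table = tab, top_list = rank_side(TRUE),
         bottom_list = rank_side(FALSE), n_samples = n, n_top = n_top,
         feature_name = feature_name, cohort = attr(expr, "cohort"),
         timepoint_mode = timepoint_mode),
    class = "association_result"
  )
}

# Pearson correlation of each rank row against the feature ranks,
# vectorised over genes; constant rows return NaN.
ranked_pearson <- function(rg, rf) {
  rfc <- rf - mean(rf)
  rgc <- rg - rowMeans(rg)
  denom <- sqrt(rowSums(rgc^2) * sum(rfc^2))
  num <- as.vector(rgc %*% rfc)
  out <- unname(num / denom)
  out[denom == 0] <- NaN
  pmin(pmax(out, -1), 1)
}

spearman_p_t <- function(rho, n) {
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1] <- 0
  pmin(p, 1)
}

# Exact two-sided p under the permutation null for untied data: the null
# distribution of rho = 1 - 6S/(n^3 - n) is enumerated once per n and
# cached.
.spearman_null_cache <- new.env(parent = emptyenv())

spearman_null_rho <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_null_cache[[key]])) {
    return(.spearman_null_cache[[key]])
  }
  perms <- all_permutations(n)
  s <- colSums((t(perms) - seq_len(n))^2)
  rho <- sort(1 - 6 * s / (n^3 - n))
  .spearman_null_cache[[key]] <- rho
  rho
}

spearman_p_exact <- function(rho, n) {
  null_rho <- spearman_null_rho(n)   # sorted
  m <- length(null_rho)
  eps <- 1e-12
  p_le <- findInterval(rho + eps, null_rho) / m
  p_ge <- (m - findInterval(rho - eps, null_rho, left.open = TRUE)) / m
  pmin(1, 2 * pmin(p_ge, p_le))
}

# All permutations of 1..n, built by vectorised insertion (rows = n!).
all_permutations <- function(n) {
  out <- matrix(1L, 1L, 1L)
  for (k in 2:n) {
    prev <- out
    blocks <- lapply(seq_len(k), function(i) {
      mapped <- prev
      mapped[mapped >= i] <- mapped[mapped >= i] + 1L
      cbind(rep(i, nrow(prev)), mapped)
    })
    out <- do.call(rbind, blocks)
  }
  out
}

#' Overlap of ranked gene lists between patient and PDX cohorts
#'
#' Venn-style summary of the selected (top or bottom) association lists:
#' genes found in both cohorts, and in each cohort only. Results computed
#' over different gene universes are compared on the shared universe with
#' a warning.
#'
#' @param patient,pdx `association_result` objects.
#' @param region `"top"` (positively associated) or `"bottom"`.
#' @return List with `counts` (`patient_only`, `pdx_only`, `shared`) and
#'   `genes` (the three gene lists).
#' @export
cohort_overlap <- function(patient, pdx, region = c("top", "bottom")) {
  region <- match.arg(region)
  stopifnot(inherits(patient, "association_result"),
            inherits(pdx, "association_result"))
  up <- patient$table$gene
  ux <- pdx$table$gene
  universe <- intersect(up, ux)
  if (!setequal(up, ux)) {
    warning("gene universes differ; overlap restricted to the ",
            length(universe), " shared genes", call. = FALSE)
  }
  pick <- function(res) {
    l <- if (region == "top") res$top_list else res$bottom_list
    l[l %in% universe]
  }
  a <- pick(patient); b <- pick(pdx)
  shared <- intersect(a, b)
  list(
    counts = list(patient_only = length(setdiff(a, b)),
                  pdx_only = length(setdiff(b, a)),
                  shared = length(shared)),
    genes = list(patient_only = setdiff(a, b), pdx_only = setdiff(b, a),
                 shared = shared)
  )
}

#' Plotting-ready volcano table for an association result
#'
#' One row per tested (non-constant) gene with the correlation, the
#' `-log10` p-value, and a significance flag at the given q-value cutoff;
#' sorted by rho.
#'
#' @param result An `association_result`.
#' @param alpha Significance threshold on the BH q-value (default 0.05).
#' @return Tibble with `gene`, `rho`, `neg_log10_p`, `significant`.
#' @export
volcano_data <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "association_result"))
  tab <- result$table
  tab <- tab[is.finite(tab$rho), , drop = FALSE]
  out <- tibble::tibble(
    gene = tab$gene, rho = tab$rho,
    neg_log10_p = -log10(tab$p_value),
    significant = tab$q_value < alpha
  )
  out[order(out$rho, method = "radix"), , drop = FALSE]
}

#' Volcano plot of per-gene association statistics
#'
#' @param result An `association_result`.
#' @param alpha q-value significance cutoff used for colouring.
#' @return A ggplot object.
#' @export
plot_volcano <- function(result, alpha = 0.05) {
  dat <- volcano_data(result, alpha = alpha)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rho, y = .data$neg_log10_p,
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Spearman rho", y = expression(-log[10] ~ p),
                  colour = sprintf("q < %.2g", alpha)) +
    ggplot2::theme_minimal()
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result> ", x$feature_name, " vs ", nrow(x$table),
      " genes over ", x$n_samples, " samples (", x$cohort, ", ",
      x$timepoint_mode, ")\n  top ", length(x$top_list), " / bottom ",
      length(x$bottom_list), " genes\n", sep = "")
  invisible(x)
}
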