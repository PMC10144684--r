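#' Generate a synthetic co-clinical cohort with known ground truth
#'
#' Builds a complete paired-cohort fixture: for every subject (patients and
#' their linked PDX models) an ellipsoidal lesion at baseline (T0) and
#' on-treatment (T1), with responders shrinking and non-responders
#' stable-to-growing, plus baseline expression matrices for both cohorts in
#' which a planted subset of genes is monotonically coupled to the
#' subject's injected volume change. Every quantity is recorded in a truth
#' table, so expected features can be recomputed analytically, and the
#' whole cohort is reproducible from `(parameters, seed)`.
#'
#' Defaults mirror a prototyping-scale co-clinical study: 21 patients
#' imaged with the four-point clinical b-set (0/100/600/800 s/mm^2) and
#' 9 PDX (three per treatment arm) with the three-point preclinical b-set
#' (0/150/700 s/mm^2), T0 and T1 studies each.
#'
#' @param n_patients,n_pdx Cohort sizes (default 21 and 9).
#' @param responder_fraction Fraction of subjects drawn as responders.
#' @param effect Volume-change fraction ranges,
#'   `list(responder = c(lo, hi), non_responder = c(lo, hi))`; responder
#'   changes must lie below non-responder changes.
#' @param n_genes Shared genes in the expression matrices.
#' @param n_planted Genes coupled to the volume change (half positively,
#'   half negatively).
#' @param planted_beta Log-scale slope of a planted gene on the
#'   standardized volume change (reference effect size 1.2, against a
#'   residual log-SD of 0.4).
#' @param n_extra_genes Patient-only genes appended to exercise gene-set
#'   harmonization.
#' @param imaging `"full"` generates voxel phantoms for every study;
#'   `"none"` generates truth and expression only (features then come from
#'   the analytic truth).
#' @param noise_sigma_dwi,noise_sigma_dce Additive Gaussian noise SDs.
#' @param seed Master integer seed.
#' @return List of class `coclin_cohort`: `subjects` (truth tibble),
#'   `manifest` (one row per imaging study), `expression`
#'   (`patient`/`pdx` baseline [expression_matrix()]s), `planted_genes`
#'   (with coupling sign), `imaging` (named list of studies or `NULL`),
#'   `params`.
#' @export
make_cohort <- function(n_patients = 21L, n_pdx = 9L,
                        responder_fraction = 0.5,
                        effect = list(responder = c(-0.7, -0.4),
                                      non_responder = c(-0.05, 0.25)),
                        n_genes = 2000L, n_planted = 50L,
                        planted_beta = 1.2, n_extra_genes = 25L,
                        imaging = c("full", "none"),
                        noise_sigma_dwi = 0, noise_sigma_dce = 0,
                        seed = 1L) {
  imaging <- match.arg(imaging)
  if (n_patients < 1L || n_pdx < 1L) stop("cohort sizes must be >= 1",
                                          call. = FALSE)
  if (responder_fraction < 0 || responder_fraction > 1) {
    stop("`responder_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (max(effect$responder) >= min(effect$non_responder)) {
    stop("responder volume changes must lie below non-responder changes",
         call. = FALSE)
  }
  set.seed(as.integer(seed))

  ids <- c(sprintf("P%02d", seq_len(n_patients)),
           sprintf("X%02d", seq_len(n_pdx)))
  cohort <- rep(c("patient", "PDX"), c(n_patients, n_pdx))
  link_id <- c(sprintf("L%02d", seq_len(n_patients)),
               sprintf("L%02d", ((seq_len(n_pdx) - 1L) %% n_patients) + 1L))
  n_sub <- n_patients + n_pdx
  responder <- rep(FALSE, n_sub)
  n_resp <- round(responder_fraction * n_sub)
  responder[sample.int(n_sub, n_resp)] <- TRUE

  draw_axes <- function(is_pdx) {
    if (is_pdx) c(stats::runif(1, 3.5, 4.5), stats::runif(2, 2.5, 3.5))
    else c(stats::runif(1, 6, 10), stats::runif(2, 4, 7))
  }
  subjects <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    is_pdx <- cohort[i] == "PDX"
    ax0 <- sort(draw_axes(is_pdx), decreasing = TRUE)
    vc <- if (responder[i]) stats::runif(1, effect$responder[1], effect$responder[2])
          else stats::runif(1, effect$non_responder[1], effect$non_responder[2])
    ax1 <- ax0 * (1 + vc)^(1 / 3)
    adc0 <- stats::runif(1, 0.8e-3, 1.2e-3)
    adc1 <- adc0 * (1 + if (responder[i]) stats::runif(1, 0.3, 0.6)
                        else stats::runif(1, -0.05, 0.1))
    ser0 <- stats::runif(1, 1.8, 3.0)
    ser1 <- if (responder[i]) max(1.05, ser0 * stats::runif(1, 0.5, 0.8))
            else ser0 * stats::runif(1, 0.9, 1.1)
    subjects[[i]] <- tibble::tibble(
      subject_id = ids[i], cohort = cohort[i], link_id = link_id[i],
      responder = responder[i], volume_change = vc,
      a0_x = ax0[1], a0_y = ax0[2], a0_z = ax0[3],
      a1_x = ax1[1], a1_y = ax1[2], a1_z = ax1[3],
      adc_t0 = adc0, adc_t1 = adc1, ser_t0 = ser0, ser_t1 = ser1,
      volume_t0 = 4 / 3 * pi * prod(ax0),
      volume_t1 = 4 / 3 * pi * prod(ax1)
    )
  }
  subjects <- do.call(rbind, subjects)

  manifest <- tibble::tibble(
    study_id = as.vector(t(outer(ids, c("T0", "T1"), paste, sep = "_"))),
    subject_id = rep(ids, each = 2L),
    cohort = rep(cohort, each = 2L),
    timepoint = rep(c("T0", "T1"), n_sub),
    study_date = rep(c("2026-01-05", "2026-02-02"), n_sub)
  )

  genes <- sprintf("G%05d", seq_len(n_genes + n_extra_genes))
  shared_genes <- genes[seq_len(n_genes)]
  planted <- sample(shared_genes, n_planted)
  planted_sign <- rep(c(1, -1), length.out = n_planted)

  make_expr <- function(sub_ids, extra) {
    vc <- subjects$volume_change[match(sub_ids, subjects$subject_id)]
    z <- if (length(vc) < 2L || stats::sd(vc) == 0) rep(0, length(vc))
         else as.vector(scale(vc))
    gg <- if (extra) genes else shared_genes
    base_mu <- stats::rnorm(length(gg), mean = 4, sd = 1)
    m <- matrix(
      exp(base_mu + stats::rnorm(length(gg) * length(sub_ids), 0, 1.5)),
      nrow = length(gg), dimnames = list(gg, sub_ids))
    for (k in seq_along(planted)) {
      g <- planted[k]
      m[g, ] <- exp(base_mu[match(g, gg)] +
                      planted_sign[k] * planted_beta * z +
                      stats::rnorm(length(sub_ids), 0, 0.4))
    }
    m
  }
  expr_patient <- expression_matrix(
    make_expr(ids[cohort == "patient"], extra = TRUE),
    cohort = "patient", timepoint = "T0")
  expr_pdx <- expression_matrix(
    make_expr(ids[cohort == "PDX"], extra = FALSE),
    cohort = "PDX", timepoint = "T0")

  imaging_list <- NULL
  if (imaging == "full") {
    study_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_sub)
    imaging_list <- vector("list", 2L * n_sub)
    names(imaging_list) <- manifest$study_id
    for (r in seq_len(nrow(manifest))) {
      i <- match(manifest$subject_id[r], subjects$subject_id)
      tp <- manifest$timepoint[r]
      is_pdx <- subjects$cohort[i] == "PDX"
      grid <- c(24L, 24L, 12L)
      spacing <- if (is_pdx) c(0.45, 0.45, 0.9) else c(1.25, 1.25, 2.5)
      center <- grid * spacing / 2
      ax <- if (tp == "T0") c(subjects$a0_x[i], subjects$a0_y[i], subjects$a0_z[i])
            else c(subjects$a1_x[i], subjects$a1_y[i], subjects$a1_z[i])
      truth <- phantom_truth(
        center = center, semiaxes = ax,
        adc = if (tp == "T0") subjects$adc_t0[i] else subjects$adc_t1[i],
        ser = if (tp == "T0") subjects$ser_t0[i] else subjects$ser_t1[i])
      dwi <- make_dwi_phantom(
        truth,
        b_values = if (is_pdx) c(0, 150, 700) else c(0, 100, 600, 800),
        grid = grid, spacing = spacing, noise_sigma = noise_sigma_dwi,
        seed = study_seeds[2L * r - 1L])
      dce <- make_dce_phantom(
        truth, grid = grid, spacing = spacing,
        noise_sigma = noise_sigma_dce, seed = study_seeds[2L * r])
      dwi$mask$label <- paste0(manifest$subject_id[r], " lesion")
      imaging_list[[manifest$study_id[r]]] <-
        list(truth = truth, dwi = dwi$series, dce = dce$series,
             mask = dwi$mask)
    }
  }

  structure(
    list(subjects = subjects, manifest = manifest,
         expression = list(patient = expr_patient, pdx = expr_pdx),
         planted_genes = tibble::tibble(gene = planted, sign = planted_sign),
         imaging = imaging_list,
         params = list(n_patients = n_patients, n_pdx = n_pdx,
                       responder_fraction = responder_fraction,
                       effect = effect, n_genes = n_genes,
                       n_planted = n_planted, planted_beta = planted_beta,
                       n_extra_genes = n_extra_genes, imaging = imaging,
                       noise_sigma_dwi = noise_sigma_dwi,
                       noise_sigma_dce = noise_sigma_dce,
                       seed = as.integer(seed))),
    class = "coclin_cohort"
  )
}

#' @export
print.coclin_cohort <- function(x, ...) {
  cat("<coclin_cohort> ", x$params$n_patients, " patients + ",
      x$params$n_pdx, " PDX, ", nrow(x$manifest), " imaging studies (",
      x$params$imaging, "), ", nrow(x$expression$patient),
      "-gene patient expression\n", sep = "")
  invisible(x)
}
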