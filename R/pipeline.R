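#' Write a synthetic cohort to disk as a file-based study
#'
#' Exports every imaging study (DWI/DCE NIfTI + sidecars, mask NIfTI), the
#' baseline expression TSVs, and a `manifest.json` tying each file to its
#' subject, timepoint, and generation seed.
#'
#' @param cohort A `coclin_cohort` from [make_cohort()] with
#'   `imaging = "full"`.
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "coclin_cohort"))
  if (is.null(cohort$imaging)) {
    stop("cohort was generated without imaging", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(cohort$manifest))
  for (r in seq_len(nrow(cohort$manifest))) {
    sid <- cohort$manifest$study_id[r]
    st <- cohort$imaging[[sid]]
    dwi <- file.path(dir, paste0(sid, "_dwi.nii.gz"))
    dce <- file.path(dir, paste0(sid, "_dce.nii.gz"))
    msk <- file.path(dir, paste0(sid, "_mask.nii.gz"))
    write_series(st$dwi, dwi)
    write_series(st$dce, dce)
    write_mask(st$mask, msk)
    rows[[r]] <- c(as.list(cohort$manifest[r, ]),
                   list(dwi = basename(dwi), dce = basename(dce),
                        mask = basename(msk)))
  }
  write_expression_tsv(cohort$expression$patient,
                       file.path(dir, "expression_patient_T0.tsv"))
  write_expression_tsv(cohort$expression$pdx,
                       file.path(dir, "expression_pdx_T0.tsv"))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(studies = rows,
         expression = list(patient = "expression_patient_T0.tsv",
                           pdx = "expression_pdx_T0.tsv"),
         seed = cohort$params$seed,
         version = as.character(utils::packageVersion("coclin"))),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

# Lesion features for every study, from voxel data when present, otherwise
# from the analytic truth (in-plane diameter of an axis-aligned ellipsoid =
# twice its largest in-plane semi-axis).
cohort_features <- function(cohort) {
  subj <- cohort$subjects
  man <- cohort$manifest
  out <- vector("list", nrow(man))
  for (r in seq_len(nrow(man))) {
    sid <- man$study_id[r]
    tp <- man$timepoint[r]
    i <- match(man$subject_id[r], subj$subject_id)
    if (!is.null(cohort$imaging)) {
      st <- cohort$imaging[[sid]]
      if (is.null(st) || is.null(st$mask)) {
        stop("feature extraction failed: no mask for subject ",
             man$subject_id[r], " at ", tp, call. = FALSE)
      }
      adc_map <- fit_adc_map(st$dwi, st$mask)
      ser_map <- compute_ser_map(st$dce, st$mask)
      f <- extract_lesion_features(
        st$mask, adc_map, ser_map, subject_id = man$subject_id[r],
        timepoint = tp, cohort = man$cohort[r],
        study_date = man$study_date[r])
    } else {
      ax <- if (tp == "T0") c(subj$a0_x[i], subj$a0_y[i], subj$a0_z[i])
            else c(subj$a1_x[i], subj$a1_y[i], subj$a1_z[i])
      adc <- if (tp == "T0") subj$adc_t0[i] else subj$adc_t1[i]
      ser <- if (tp == "T0") subj$ser_t0[i] else subj$ser_t1[i]
      f <- tibble::tibble(
        subject_id = man$subject_id[r], cohort = man$cohort[r],
        lesion_label = paste0(man$subject_id[r], " lesion"), timepoint = tp,
        longest_diameter = 2 * max(ax[1:2]),
        volume = 4 / 3 * pi * prod(ax),
        adc_mean = adc, adc_median = adc, ser_mean = ser, ser_median = ser,
        modality = "MRI", study_date = man$study_date[r])
    }
    out[[r]] <- f
  }
  do.call(rbind, out)
}

#' Run the co-clinical analysis pipeline end to end
#'
#' Chains the stages over a synthetic (or loaded) cohort: parameter-map
#' fitting and lesion feature extraction for every study, per-cohort
#' response tables and waterfall orderings for the selected feature,
#' on-treatment expression simulation, gene-set harmonization, and the
#' imaging-omics Spearman association of the feature's baseline-relative
#' change with baseline expression in both cohorts, ending with the
#' top/bottom-list overlap and volcano tables. All outputs are plain text
#' (CSV/TSV/JSON) and byte-identical across reruns with the same cohort
#' and seed; a `run_log.json` records parameters, seeds, and version.
#'
#' @param cohort A `coclin_cohort`.
#' @param out_dir Results directory (created).
#' @param feature Imaging feature driving response and association.
#' @param n_top Association list size.
#' @param sim_seed Seed for the on-treatment expression simulation
#'   (defaults to the cohort seed + 1).
#' @return Invisibly, a list with the in-memory stage results
#'   (`features`, `response`, `waterfall`, `simulation`, `association`,
#'   `overlap`).
#' @export
run_pipeline <- function(cohort, out_dir, feature = "volume",
                         n_top = 500L, sim_seed = NULL) {
  stopifnot(inherits(cohort, "coclin_cohort"))
  if (is.null(sim_seed)) sim_seed <- cohort$params$seed + 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, name) utils::write.csv(
    d, file.path(out_dir, name), row.names = FALSE, quote = FALSE)
  wtsv <- function(d, name) utils::write.table(
    d, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)

  feats <- cohort_features(cohort)
  wcsv(feats, "lesion_features.csv")

  resp <- build_response_table(feats, feature_name = feature)
  wf <- waterfall_order(resp$records)
  wcsv(resp$records, "response_table.csv")
  wcsv(resp$exclusions, "response_exclusions.csv")
  wcsv(wf, "waterfall.csv")

  sims <- list(
    patient = simulate_on_treatment(cohort$expression$patient, sim_seed),
    pdx = simulate_on_treatment(cohort$expression$pdx, sim_seed + 1L))
  write_expression_tsv(sims$patient$t1,
                       file.path(out_dir, "expression_patient_T1.tsv"))
  write_expression_tsv(sims$pdx$t1,
                       file.path(out_dir, "expression_pdx_T1.tsv"))
  write_factor_assignment(sims$patient$assignment,
                          file.path(out_dir, "factors_patient"))
  write_factor_assignment(sims$pdx$assignment,
                          file.path(out_dir, "factors_pdx"))

  harm <- harmonize_gene_sets(cohort$expression$patient,
                              cohort$expression$pdx)

  rr <- stats::setNames(resp$records$response_rate, resp$records$subject_id)
  assoc <- list(
    patient = spearman_associate(
      harm$a, rr[colnames(harm$a)], n_top = n_top,
      feature_name = paste0("delta_", feature), timepoint_mode = "delta"),
    pdx = spearman_associate(
      harm$b, rr[colnames(harm$b)], n_top = n_top,
      feature_name = paste0("delta_", feature), timepoint_mode = "delta"))
  wtsv(assoc$patient$table, "association_patient.tsv")
  wtsv(assoc$pdx$table, "association_pdx.tsv")
  wtsv(volcano_data(assoc$patient), "volcano_patient.tsv")
  wtsv(volcano_data(assoc$pdx), "volcano_pdx.tsv")

  overlap <- list(top = cohort_overlap(assoc$patient, assoc$pdx, "top"),
                  bottom = cohort_overlap(assoc$patient, assoc$pdx,
                                          "bottom"))
  jsonlite::write_json(
    list(top = overlap$top$counts, bottom = overlap$bottom$counts),
    file.path(out_dir, "overlap.json"), auto_unbox = TRUE, digits = NA)

  jsonlite::write_json(
    list(version = as.character(utils::packageVersion("coclin")),
         cohort_seed = cohort$params$seed, sim_seed = sim_seed,
         feature = feature, n_top = n_top,
         r2_patient = unname(sims$patient$r2),
         r2_pdx = unname(sims$pdx$r2),
         n_studies = nrow(cohort$manifest)),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  invisible(list(features = feats, response = resp, waterfall = wf,
                 simulation = sims, association = assoc, overlap = overlap))
}
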