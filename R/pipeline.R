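#' Analysis configuration
#'
#' Bundles every setting of the two-stage group analysis: the cohort source
#' (a `dcm_cohort`, a directory written by [write_cohort()], or a
#' `dcm_cohort_spec` to simulate), the model families, inversion settings,
#' BMS settings and group-statistics settings.
#'
#' @param cohort a `dcm_cohort`, a `dcm_cohort_spec`, or a path to a cohort
#'   directory.
#' @param regions region set (default [auditory_regions()]).
#' @param input_candidates named list of input-region sets for stage 1;
#'   default the bilateral-HG ("input_HG") and bilateral-STG ("input_STG")
#'   candidates.
#' @param bilinear_variants,nonlinear_variants family descriptors for stage
#'   2 (defaults as in [build_bilinear_family()] /
#'   [build_nonlinear_family()]).
#' @param fit inversion settings ([fit_settings()]).
#' @param alpha0 Dirichlet prior counts for BMS.
#' @param exceedance_method,n_samples,bms_seed exceedance settings (see
#'   [exceedance_prob()]).
#' @param family_alpha,P_min group-statistics settings (see
#'   [connection_stats()]).
#' @param out_dir optional directory; when set, every stage writes its
#'   report tables there.
#' @return A list of class `dcm_config`.
#' @export
analysis_config <- function(cohort,
                            regions = auditory_regions(),
                            input_candidates = list(
                              input_HG = c("LHG", "RHG"),
                              input_STG = c("LSTG", "RSTG")),
                            bilinear_variants = NULL,
                            nonlinear_variants = NULL,
                            fit = fit_settings(),
                            alpha0 = 1,
                            exceedance_method = "auto",
                            n_samples = 1e6, bms_seed = 1L,
                            family_alpha = 0.05, P_min = 0.9,
                            out_dir = NULL) {
  if (is.character(cohort)) {
    if (!file.exists(file.path(cohort, "manifest.yaml"))) {
      stop("cohort directory not found or missing manifest: ", cohort)
    }
  }
  structure(list(cohort = cohort, regions = regions,
                 input_candidates = input_candidates,
                 bilinear_variants = bilinear_variants,
                 nonlinear_variants = nonlinear_variants,
                 fit = fit, alpha0 = alpha0,
                 exceedance_method = exceedance_method,
                 n_samples = n_samples, bms_seed = bms_seed,
                 family_alpha = family_alpha, P_min = P_min,
                 out_dir = out_dir),
            class = "dcm_config")
}

resolve_cohort <- function(config) {
  ch <- config$cohort
  if (inherits(ch, "dcm_cohort")) return(ch)
  if (inherits(ch, "dcm_cohort_spec")) return(simulate_cohort(ch))
  if (is.character(ch)) {
    rc <- read_cohort(ch)
    return(structure(list(subjects = rc$subjects, paradigm = rc$paradigm,
                          truth = NULL, cohort_spec = NULL),
                     class = "dcm_cohort"))
  }
  stop("unsupported cohort source")
}

# Fit a list of specs to every subject; failed subjects (both-model
# divergence) are flagged and dropped so the evidence table stays complete.
fit_cohort <- function(subjects, specs, settings) {
  K <- length(specs)
  fits <- vector("list", length(subjects))
  ok <- logical(length(subjects))
  for (i in seq_along(subjects)) {
    row <- vector("list", K)
    failed <- FALSE
    for (k in seq_len(K)) {
      row[[k]] <- tryCatch(
        fit_dcm(subjects[[i]], specs[[k]], settings = settings),
        error = function(e) {
          warning("subject ", subjects[[i]]$id, ", model '", specs[[k]]$name,
                  "' failed: ", conditionMessage(e))
          NULL
        })
      if (is.null(row[[k]])) { failed <- TRUE; break }
    }
    fits[[i]] <- row
    ok[i] <- !failed
  }
  list(fits = fits[ok], ok = ok,
       excluded = vapply(subjects[!ok], function(s) s$id, character(1)))
}

evidence_from_fits <- function(fits, specs, subjects_ids) {
  F <- t(vapply(fits, function(row) vapply(row, free_energy, numeric(1)),
                numeric(length(specs))))
  F <- matrix(F, ncol = length(specs))
  log_evidence_table(F, subjects = subjects_ids,
                     models = vapply(specs, function(s) s$name, character(1)))
}

#' Stage 1: input-region determination and connection pruning
#'
#' Fits the fully connected input-candidate models to every subject,
#' compares them with random-effects BMS, computes group connection
#' statistics on the winning model's posterior means, and prunes connections
#' with the dual criterion (Bonferroni-corrected one-sample t-test and mean
#' posterior probability).
#'
#' @param config a `dcm_config`.
#' @return A list of class `dcm_stage_report`: `stage`, `specs`, `fits` (per
#'   subject, per model), `evidence`, `bms`, `winner` (spec), `stats`
#'   (connection table), `pruned` (pruned `dcm_model_spec`), `excluded`.
#' @export
run_stage1 <- function(config) {
  cohort <- resolve_cohort(config)
  specs <- lapply(names(config$input_candidates), function(nm) {
    build_fully_connected(config$regions, config$input_candidates[[nm]],
                          name = nm)
  })
  fc <- fit_cohort(cohort$subjects, specs, config$fit)
  if (length(fc$fits) == 0) stop("stage 1: all subjects failed")
  ids <- vapply(cohort$subjects, function(s) s$id, character(1))[fc$ok]
  ev <- evidence_from_fits(fc$fits, specs, ids)
  bms <- rfx_bms(ev, alpha0 = config$alpha0,
                 exceedance_method = config$exceedance_method,
                 n_samples = config$n_samples, seed = config$bms_seed)
  win_k <- which.max(bms$phi)
  winner <- specs[[win_k]]
  stats <- connection_stats(lapply(fc$fits, `[[`, win_k),
                            family_alpha = config$family_alpha,
                            P_min = config$P_min)
  retained <- prune_connections(stats, attr(stats, "threshold"), config$P_min)
  pruned <- pruned_spec_from_stats(winner, retained, name = "pruned_winner")
  report <- structure(list(stage = "stage1", specs = specs, fits = fc$fits,
                           evidence = ev, bms = bms, winner = winner,
                           stats = stats, pruned = pruned,
                           excluded = fc$excluded),
                      class = "dcm_stage_report")
  maybe_write_stage(report, config)
  report
}

#' Stage 2: bilinear vs non-linear model families
#'
#' Builds the default six-member bilinear and six-member non-linear families
#' on the pruned skeleton, fits all twelve models to every subject, selects
#' each family's winner by within-family RFX BMS, and compares the two
#' winners head to head (K = 2).
#'
#' @param config a `dcm_config`.
#' @param pruned the pruned `dcm_model_spec` from stage 1.
#' @return A list of class `dcm_stage_report`: `specs`, `fits`, `evidence`,
#'   `bms_bilinear`, `bms_nonlinear`, `bms_head_to_head`, `winner`
#'   (final spec), `family_winner` (named indices), `excluded`.
#' @export
run_stage2 <- function(config, pruned) {
  cohort <- resolve_cohort(config)
  bil <- if (is.null(config$bilinear_variants)) {
    build_bilinear_family(pruned)
  } else build_bilinear_family(pruned, config$bilinear_variants)
  nl <- if (is.null(config$nonlinear_variants)) {
    build_nonlinear_family(pruned)
  } else build_nonlinear_family(pruned, config$nonlinear_variants)
  specs <- c(bil, nl)
  fc <- fit_cohort(cohort$subjects, specs, config$fit)
  if (length(fc$fits) == 0) stop("stage 2: all subjects failed")
  ids <- vapply(cohort$subjects, function(s) s$id, character(1))[fc$ok]
  ev <- evidence_from_fits(fc$fits, specs, ids)
  kb <- seq_along(bil)
  kn <- length(bil) + seq_along(nl)
  bms_b <- rfx_bms(log_evidence_table(ev$F[, kb, drop = FALSE]),
                   alpha0 = config$alpha0,
                   exceedance_method = config$exceedance_method,
                   n_samples = config$n_samples, seed = config$bms_seed)
  bms_n <- rfx_bms(log_evidence_table(ev$F[, kn, drop = FALSE]),
                   alpha0 = config$alpha0,
                   exceedance_method = config$exceedance_method,
                   n_samples = config$n_samples, seed = config$bms_seed)
  wb <- kb[which.max(bms_b$phi)]
  wn <- kn[which.max(bms_n$phi)]
  bms_hh <- rfx_bms(log_evidence_table(ev$F[, c(wb, wn), drop = FALSE]),
                    alpha0 = config$alpha0,
                    exceedance_method = config$exceedance_method,
                    n_samples = config$n_samples, seed = config$bms_seed)
  final_k <- c(wb, wn)[which.max(bms_hh$phi)]
  report <- structure(list(stage = "stage2", specs = specs, fits = fc$fits,
                           evidence = ev,
                           bms_bilinear = bms_b, bms_nonlinear = bms_n,
                           bms_head_to_head = bms_hh,
                           family_winner = c(bilinear = wb, nonlinear = wn),
                           winner = specs[[final_k]],
                           excluded = fc$excluded),
                      class = "dcm_stage_report")
  maybe_write_stage(report, config)
  report
}

#' Run the full two-stage analysis
#'
#' @param config a `dcm_config`.
#' @return A list of class `dcm_report_bundle` with `stage1`, `stage2`, and
#'   `final_model` (the head-to-head winner's spec).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "dcm_config"))
  s1 <- run_stage1(config)
  s2 <- run_stage2(config, s1$pruned)
  structure(list(stage1 = s1, stage2 = s2, final_model = s2$winner),
            class = "dcm_report_bundle")
}

#' @export
print.dcm_stage_report <- function(x, ...) {
  cat(sprintf("<dcm_stage_report> %s\n", x$stage))
  if (x$stage == "stage1") {
    print(x$bms)
    cat("retained connections:",
        paste(sprintf("%s->%s", x$stats$source[x$stats$retained],
                      x$stats$target[x$stats$retained]), collapse = ", "),
        "\n")
  } else {
    cat("head-to-head:\n"); print(x$bms_head_to_head)
    cat("final model:", x$winner$name, "\n")
  }
  invisible(x)
}

#' @export
print.dcm_report_bundle <- function(x, ...) {
  print(x$stage1); print(x$stage2)
  invisible(x)
}

maybe_write_stage <- function(report, config) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(config$out_dir, report$stage)
  write_log_evidence(report$evidence, paste0(pre, "_evidence.tsv"))
  if (report$stage == "stage1") {
    write_bms_report(report$bms, paste0(pre, "_bms.yaml"))
    write_connection_stats(report$stats, paste0(pre, "_connection_stats.tsv"))
    write_model_spec(report$pruned, paste0(pre, "_pruned_model.yaml"))
  } else {
    write_bms_report(report$bms_bilinear, paste0(pre, "_bms_bilinear.yaml"))
    write_bms_report(report$bms_nonlinear, paste0(pre, "_bms_nonlinear.yaml"))
    write_bms_report(report$bms_head_to_head, paste0(pre, "_bms_head_to_head.yaml"))
    write_model_spec(report$winner, paste0(pre, "_final_model.yaml"))
  }
  invisible(NULL)
}
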