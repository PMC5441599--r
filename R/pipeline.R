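#' Run the FCS analysis pipeline on a photon stream
#'
#' The experimental-side protocol: correlate the photon stream (cross-
#' correlation between the two detector channels when both are present)
#' with ten-segment standard errors, fit the composite FCS model with one
#' and with two dynamic components, compare the two fits, isolate the
#' dynamic part of the correlation, and convert the dynamic amplitude and
#' relaxation time to microscopic contact formation/dissociation rates.
#'
#' @param input a [photon_stream()] or a [photon_sim_params()] (which is
#'   simulated first).
#' @param config list of settings: `correlate` (passed to
#'   [segment_errors()]: `n_segments`, `m`, `base_bin_s`, `max_lag_s`),
#'   `fit` (passed to [fit_fcs()]: `triplet`, `antibunching`, `p_free`,
#'   `start`, `fixed`), `alpha` (model comparison threshold),
#'   `convention` (rate convention), `use_components` (force `1` or `2`
#'   dynamic components instead of the F-test recommendation).
#' @param out_dir optional directory; when given, the correlation curve,
#'   fit reports and the report JSON are written there.
#' @return object of class `fcs_pipeline_result`: the curve, both fits,
#'   the model comparison, the isolated dynamic curve, the combined
#'   dynamic parameters and rates, and provenance.
#' @export
run_fcs_pipeline <- function(input, config = list(), out_dir = NULL) {
  if (inherits(input, "photon_sim_params")) {
    stream <- simulate_photons(input)
    provenance <- list(input = "simulated", seed = input$seed,
                       sim_params = input[setdiff(names(input),
                                                  "positions_nm")])
  } else if (inherits(input, "photon_stream")) {
    stream <- input
    provenance <- list(input = "stream")
  } else stop("input must be a photon_stream or photon_sim_params")

  two_channel <- length(unique(stream$channel)) == 2L
  cor_args <- config$correlate %||% list()
  cor_args$mode <- if (two_channel) "cross" else "auto"
  curve <- do.call(segment_errors, c(list(stream), cor_args))

  fit_args <- config$fit %||% list()
  fit1 <- do.call(fit_fcs, c(list(curve, n_dyn = 1L), fit_args))
  fit2 <- do.call(fit_fcs, c(list(curve, n_dyn = 2L), fit_args))
  alpha <- config$alpha %||% 0.05
  cmp <- compare_fits_f(fit1, fit2, alpha)

  n_comp <- config$use_components %||%
    (if (cmp$preferred == "two_component") 2L else 1L)
  chosen <- if (n_comp == 2L) fit2 else fit1
  dyn_curve <- isolate_dynamic(curve, chosen$params)

  convention <- config$convention %||% "as_printed"
  est <- chosen$estimate
  if (n_comp == 2L) {
    comb <- combine_two_component(est["a_r1"], est["tau_r1_s"],
                                  est["a_r2"], est["tau_r2_s"])
    a_r <- comb$a_total
    tau_r_s <- comb$tau_avg_s
  } else {
    a_r <- unname(est["a_r1"])
    tau_r_s <- unname(est["tau_r1_s"])
  }
  rates <- rates_from_dynamics(a_r, tau_r_s, convention)

  result <- structure(
    list(curve = curve, fit1 = fit1, fit2 = fit2, comparison = cmp,
         n_components = n_comp, dynamic_curve = dyn_curve,
         a_r = a_r, tau_r_s = tau_r_s, rates = rates,
         provenance = c(provenance,
                        list(settings = config,
                             n_photons = length(stream$tick)))),
    class = "fcs_pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_correlation(curve, file.path(out_dir, "correlation.tsv"))
    write_correlation(dyn_curve, file.path(out_dir, "dynamic_part.tsv"))
    write_fit_report(chosen, file.path(out_dir, "fcs_fit.json"))
    writeLines(report_json(comparison_report(fcs = result)),
               file.path(out_dir, "fcs_report.json"))
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard scaled-down parameter-recovery conditions
#'
#' The simulation and analysis settings used for photon-pipeline
#' parameter-recovery studies: one particle on average in a 195 nm focus
#' (axial ratio 5), a diffusion time of about 50 us, triplet blinking
#' (fraction 0.25 at 2.4 us), and two-state quenching dynamics
#' slowed to a 200 ns relaxation time so that a quarter-second synthetic
#' measurement resolves every process with well-separated timescales
#' (tau_r : tau_T : tau_D of about 1 : 12 : 250). The fit holds the
#' calibrated axial ratio fixed and restricts the triplet time to the
#' microsecond range and the quenching terms below it, since the triplet
#' and quenching factors share one functional form and would otherwise
#' exchange roles.
#'
#' @param seed integer seed for the replicate.
#' @return list with `sim` (a [photon_sim_params()]) and `config` (for
#'   [run_fcs_pipeline()]).
#' @export
fcs_recovery_conditions <- function(seed = 1L) {
  list(
    sim = photon_sim_params(
      N = 1, w_nm = 195, p = 5, D_um2_s = 190, brightness_cps = 1.5e6,
      T_frac = 0.25, tau_T_us = 2.4,
      quench = list(k_form = 2.5, k_diss = 2.5),
      duration_s = 0.3, tick_ps = 16, split = TRUE, seed = seed),
    config = list(
      correlate = list(n_segments = 10L, m = 16L, base_bin_s = 32e-9,
                       max_lag_s = 5e-4),
      fit = list(triplet = TRUE, fixed = c(p = 5),
                 start = list(tau_D_s = 3e-5, T_frac = 0.15,
                              tau_T_s = 2e-6, a_r1 = 0.8,
                              tau_r1_s = 1.5e-7),
                 lower = c(tau_T_s = 8e-7),
                 upper = c(tau_T_s = 1e-5, tau_r1_s = 8e-7,
                           tau_r2_s = 8e-7)),
      convention = "telegraph_oracle"))
}

# Nested F-test between two already-computed fcs_fit objects.
compare_fits_f <- function(fit1, fit2, alpha = 0.05) {
  df1 <- fit1$n_lags - fit1$n_free
  df2 <- fit2$n_lags - fit2$n_free
  ddf <- df1 - df2
  if (ddf > 0 && df2 > 0 && fit2$chisq > 0) {
    F_stat <- ((fit1$chisq - fit2$chisq) / ddf) / (fit2$chisq / df2)
    p_value <- if (F_stat > 0) pf(F_stat, ddf, df2, lower.tail = FALSE)
               else 1
  } else {
    F_stat <- NA_real_; p_value <- NA_real_
  }
  list(redchisq = c(one = fit1$redchisq, two = fit2$redchisq),
       F_stat = F_stat, p_value = p_value, alpha = alpha,
       preferred = if (!is.na(p_value) && p_value < alpha &&
                       fit2$converged) "two_component" else "one_component")
}

#' Run the MD analysis pipeline on a trajectory or quench signal
#'
#' The simulation-side protocol: classify frames into dark/fluorescent
#' states by the ring-center distance criterion, compute the quenching
#' autocorrelation and its two-state fit over the full analysis window and
#' again discarding an initial equilibration period, convert to rates, and
#' (when coordinates are available) compute the end-to-end distance
#' regimes with their transition statistics and optionally a clustering
#' summary.
#'
#' @param input a [trajectory_ensemble()] or a binary [state_sequence()]
#'   (a precomputed quench signal).
#' @param config list: `criterion` (a [quench_criterion()], required for
#'   ensembles), `thresholds` (a [regime_thresholds()]),
#'   `equilibration_offset_s` (default 0: no post-equilibration window),
#'   `convention`, `cluster` (logical; run [single_linkage_cluster()]),
#'   `cutoff_nm`, `max_lag_s`, `min_pairs`.
#' @param out_dir optional artifact directory.
#' @return object of class `md_pipeline_result` with `full` and (when an
#'   offset is set) `post_eq` quench fits and rates, `transitions`, and
#'   optionally `clusters`.
#' @export
run_md_pipeline <- function(input, config = list(), out_dir = NULL) {
  convention <- config$convention %||% "as_printed"
  offset <- config$equilibration_offset_s %||% 0
  if (inherits(input, "trajectory_ensemble")) {
    if (is.null(config$criterion)) {
      stop("config$criterion (quench_criterion) is required for ensembles")
    }
    states <- quench_series(input, config$criterion)
    ee <- end_to_end_series(input,
                            config$thresholds %||% regime_thresholds())
    transitions <- count_transitions(ee$states)
    clusters <- if (isTRUE(config$cluster)) {
      single_linkage_cluster(input,
                             cutoff_nm = config$cutoff_nm %||% 0.25)
    }
  } else if (inherits(input, "state_sequence") && input$kind == "binary") {
    states <- input
    ee <- NULL; transitions <- NULL; clusters <- NULL
  } else {
    stop("input must be a trajectory_ensemble or a binary state_sequence")
  }
  total <- duration_s(states)
  if (offset < 0 || offset >= total) {
    stop("equilibration offset must lie inside the signal ",
         "(zero-length analysis window)")
  }
  qa_args <- list(max_lag_s = config$max_lag_s,
                  min_pairs = config$min_pairs %||% 100,
                  convention = convention)
  qa_args <- qa_args[!vapply(qa_args, is.null, logical(1))]
  full <- do.call(quench_autocorrelation, c(list(states), qa_args))
  post_eq <- if (offset > 0) {
    do.call(quench_autocorrelation,
            c(list(states, start_offset_s = offset), qa_args))
  }
  result <- structure(
    list(states = states, full = full, post_eq = post_eq,
         end_to_end = ee, transitions = transitions, clusters = clusters,
         provenance = list(settings = config,
                           equilibration_offset_s = offset,
                           duration_s = total)),
    class = "md_pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_series(states, file.path(out_dir, "quench_states.tsv"))
    write_correlation(full$curve, file.path(out_dir, "quench_acf_full.tsv"))
    write_fit_report(full$fit, file.path(out_dir, "quench_fit_full.json"))
    if (!is.null(post_eq)) {
      write_correlation(post_eq$curve,
                        file.path(out_dir, "quench_acf_posteq.tsv"))
      write_fit_report(post_eq$fit,
                       file.path(out_dir, "quench_fit_posteq.json"))
    }
    writeLines(report_json(comparison_report(md = result)),
               file.path(out_dir, "md_report.json"))
  }
  result
}

dyn_fragment <- function(a_r, tau_r_s, rates) {
  list(a_r = a_r, tau_r_ns = tau_r_s / .ns,
       k_on_per_us = if (!is.null(rates)) rates$k_on_per_us,
       k_off_per_us = if (!is.null(rates)) rates$k_off_per_us,
       convention = if (!is.null(rates)) rates$convention)
}

#' Assemble a comparison report from pipeline results
#'
#' Collects the dynamic amplitudes, relaxation times, and on/off rates of
#' the experiment-style FCS analysis and the MD-style analysis (full
#' window and post-equilibration window) into one report; every rate in
#' the report is reproducible from the stored `(a_r, tau_r)` via the
#' stored convention.
#'
#' @param fcs an `fcs_pipeline_result` or `NULL`.
#' @param md an `md_pipeline_result` or `NULL`.
#' @return object of class `comparison_report`.
#' @export
comparison_report <- function(fcs = NULL, md = NULL) {
  rep <- list(generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(fcs)) {
    rep$fcs <- c(dyn_fragment(fcs$a_r, fcs$tau_r_s, fcs$rates),
                 list(n_components = fcs$n_components,
                      model_comparison = list(
                        F_stat = fcs$comparison$F_stat,
                        p_value = fcs$comparison$p_value,
                        preferred = fcs$comparison$preferred),
                      tau_D_us = unname(
                        fcs$fit1$estimate["tau_D_s"]) / .us,
                      provenance = fcs$provenance))
  }
  if (!is.null(md)) {
    f <- md$full$fit
    rep$md_full <- dyn_fragment(f$a_r, f$tau_r_s, f$rates)
    if (!is.null(md$post_eq)) {
      f2 <- md$post_eq$fit
      rep$md_post_eq <- dyn_fragment(f2$a_r, f2$tau_r_s, f2$rates)
    }
    if (!is.null(md$transitions)) {
      rep$transitions <- list(N_T = md$transitions$N_T,
                              rate_per_us = md$transitions$rate_per_us)
    }
    if (!is.null(md$clusters)) {
      rep$clusters <- list(
        n_clusters = md$clusters$n_clusters,
        populations_pct = head(md$clusters$populations_pct, 10L),
        cutoff_nm = md$clusters$cutoff_nm)
    }
    rep$md_provenance <- md$provenance
  }
  structure(rep, class = "comparison_report")
}

#' @rdname comparison_report
#' @param report a `comparison_report`.
#' @return for `report_json`, the JSON string.
#' @export
report_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                   null = "null", force = TRUE)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  show <- function(tag, fr) {
    if (is.null(fr)) return()
    cat(sprintf("  %-10s a_r = %.3g, tau_r = %.4g ns, k_on = %.3g, k_off = %.3g us^-1\n",
                tag, fr$a_r, fr$tau_r_ns,
                fr$k_on_per_us %||% NA, fr$k_off_per_us %||% NA))
  }
  show("FCS", x$fcs); show("MD all", x$md_full); show("MD post-eq", x$md_post_eq)
  if (!is.null(x$transitions)) {
    cat(sprintf("  transitions: N_T = %d, rate = %.3g us^-1\n",
                x$transitions$N_T, x$transitions$rate_per_us))
  }
  invisible(x)
}
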