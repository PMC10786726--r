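#' Pipeline configuration
#'
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it (default 17).
#' @param signature_cutoff contribution cutoff for refitting (default 0.06).
#' @param min_mutations minimum catalog size; smaller samples are excluded
#'   from refitting (default 10).
#' @param preset caller label preset (see [caller_presets()]).
#' @param out_dir output directory for tables, summary and plots (NULL = no
#'   files written).
#' @param sim a [sim_spec()] describing the simulated inputs.
#' @param signatures_path path to a signature matrix TSV; defaults to the
#'   bundled approximate SBS1/2/5/13/40 fixture.
#' @param make_plots write 96-channel profile PDFs (default TRUE when
#'   `out_dir` is set).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 17, signature_cutoff = 0.06,
                            min_mutations = 10, preset = "mouse-wes",
                            out_dir = NULL, sim = sim_spec(seed = seed),
                            signatures_path = NULL,
                            make_plots = !is.null(out_dir)) {
  if (signature_cutoff < 0 || signature_cutoff >= 1) {
    stop("signature_cutoff must be in [0, 1)")
  }
  if (min_mutations < 0) stop("min_mutations must be >= 0")
  if (is.null(signatures_path)) {
    signatures_path <- system.file("extdata", "signatures_synthetic.tsv",
                                   package = "apobecsig")
  }
  structure(list(seed = seed, signature_cutoff = signature_cutoff,
                 min_mutations = min_mutations, preset = preset,
                 out_dir = out_dir, sim = sim,
                 signatures_path = signatures_path, make_plots = make_plots),
            class = "pipeline_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Stages: simulate (reference, mutation catalog, caller evidence, paired
#' cohort, multi-region copy-number profiles) -> filter (somatic cascade +
#' germline) -> contexts (TCN/TCW/RTCW/YTCW classification) -> catalog ->
#' signature refit -> CIN metrics -> statistics. One structured log line per
#' stage reports counts in/out. Output is a pure function of the
#' configuration (including its seed).
#'
#' @param config a [pipeline_config()].
#' @return Invisible list with all stage results and `summary` (the JSON-able
#'   metrics summary). When `config$out_dir` is set, writes `variants.vcf`,
#'   `filter_decisions.tsv`, `contexts.tsv`, `catalog96.tsv`,
#'   `exposures.tsv`, `segments.tsv`, `summary.json` and (optionally)
#'   `profile96_<sample>.pdf` there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  signatures <- read_signature_matrix(cfg$signatures_path)

  # --- simulate ---------------------------------------------------------
  ref <- simulate_reference(cfg$sim$genome_length, cfg$sim$gc_fraction,
                            seed = cfg$seed)
  truth <- simulate_catalog(ref, signatures, cfg$sim, sample_id = "tumor1")
  calls <- simulate_caller_calls(truth, cfg$sim$evidence,
                                 seed = cfg$seed + 1L)
  stage_log("simulate", nrow(truth), " true variants, ", nrow(calls),
            " detected by >=1 caller")
  segments <- simulate_multiregion_segments(cfg$sim, tumor_id = "tumor1")
  cohort <- simulate_paired_cohort(
    ref, signatures, cfg$sim,
    burst = list(n_extra = 50, tcw_only = TRUE, ct_cg_odds = 2),
    n_patients = 8, seed = cfg$seed + 2L)

  # --- filter -----------------------------------------------------------
  dec_somatic <- filter_snv_mouse(calls, preset = cfg$preset)
  dec_germline <- filter_germline(calls)
  keep <- dec_somatic$passed & !dec_somatic$error &
    dec_germline$passed & !dec_germline$error
  filtered <- calls[keep, , drop = FALSE]
  stage_log("filter", nrow(calls), " in, ", nrow(filtered), " pass (",
            sum(!dec_somatic$passed & !dec_somatic$error), " somatic-rule, ",
            sum(!dec_germline$passed & !dec_germline$error),
            " germline fails)")

  # --- contexts ---------------------------------------------------------
  ctx <- extract_context(ref, filtered)
  fr <- apobec_fractions(ctx)
  cnt <- count_apobec_mutations(ctx, stratify_by_clonality = TRUE)
  stage_log("contexts", nrow(ctx), " classified, ",
            attr(ctx, "n_no_context"), " without context; TCW fraction ",
            sprintf("%.3f", fr$frac_tcw))

  # --- catalog + refit --------------------------------------------------
  catalog <- build_catalog96(ctx)
  fit <- refit_signatures(catalog, signatures, cutoff = cfg$signature_cutoff,
                          min_mutations = cfg$min_mutations)
  dom <- if (fit$excluded) NULL else dominant_signature(fit)
  burden <- if (fit$excluded) NA_real_ else apobec_signature_burden(fit)
  stage_log("signatures", sum(catalog), " mutations refit; ",
            if (fit$excluded) "sample excluded" else
              paste0("dominant ", dom$signature, ", APOBEC burden ", burden))

  # paired cohort burden change (pre vs post)
  pre_counts <- vapply(cohort, function(p)
    count_apobec_mutations(extract_context(ref, p$pre))$n_apobec, numeric(1))
  post_counts <- vapply(cohort, function(p)
    count_apobec_mutations(extract_context(ref, p$post))$n_apobec, numeric(1))
  paired_test <- wilcoxon_signed_rank_exact(x = post_counts, y = pre_counts,
                                            alternative = "two.sided")
  stage_log("cohort", length(cohort), " pairs; median APOBEC gain ",
            stats::median(post_counts - pre_counts), ", signed-rank p ",
            format(paired_test$p_value, digits = 4))

  # --- CIN metrics ------------------------------------------------------
  ith <- scna_ith(segments)
  stage_log("cin", "SCNA ITH ", sprintf("%.4f", ith$ith), " (",
            ith$heterogeneous_bp, "/", ith$altered_bp, " bp)")

  # --- summary ----------------------------------------------------------
  excl <- list(excluded = fit$excluded,
               reason = if (fit$excluded) fit$exclusion_reason else NA)
  summary <- list(
    seed = cfg$seed,
    n_true_variants = nrow(truth),
    n_called = nrow(calls),
    n_pass_filter = nrow(filtered),
    apobec_fractions = fr[c("frac_tcn", "frac_tcw", "frac_rtcw", "frac_ytcw")],
    apobec_counts = list(total = cnt$n_total, apobec = cnt$n_apobec,
                         clonal_apobec = unname(cnt$by_clonality["clonal", "APOBEC"]),
                         subclonal_apobec = unname(cnt$by_clonality["subclonal", "APOBEC"])),
    refit = list(excluded = excl$excluded, reason = excl$reason,
                 weights = if (fit$excluded) NULL else as.list(round(fit$weights, 6)),
                 cosine_similarity = if (fit$excluded) NULL else
                   round(fit$cosine_similarity, 6),
                 dominant = if (fit$excluded) NULL else dom$signature,
                 apobec_burden = burden),
    paired_cohort = list(n_patients = length(cohort),
                         median_apobec_gain =
                           stats::median(post_counts - pre_counts),
                         signed_rank_p = paired_test$p_value),
    scna_ith = ith
  )
  res <- list(config = cfg, reference = ref, truth = truth, calls = calls,
              decisions_somatic = dec_somatic, decisions_germline = dec_germline,
              filtered = filtered, contexts = ctx, catalog = catalog,
              fit = fit, cohort = cohort, segments = segments,
              summary = summary)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_variants(filtered, file.path(cfg$out_dir, "variants.vcf"), "vcf")
    utils::write.table(dec_somatic,
                       file.path(cfg$out_dir, "filter_decisions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ctx, file.path(cfg$out_dir, "contexts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(channel = names(catalog), count = as.integer(catalog)),
      file.path(cfg$out_dir, "catalog96.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(signature = names(fit$weights), weight = fit$weights),
      file.path(cfg$out_dir, "exposures.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_segments(segments, file.path(cfg$out_dir, "segments.tsv"))
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         na = "null")
    if (isTRUE(cfg$make_plots)) {
      grDevices::pdf(file.path(cfg$out_dir, "profile96_tumor1.pdf"),
                     width = 12, height = 4)
      plot_profile96(catalog, main = "tumor1")
      grDevices::dev.off()
    }
    stage_log("write", "outputs under ", cfg$out_dir)
  }
  invisible(res)
}

#' Plot a 96-channel mutational profile
#'
#' Standard layout: 96 bars grouped into the six pyrimidine substitution
#' classes with the conventional class colors.
#'
#' @param catalog 96-vector of counts (see [build_catalog96()]).
#' @param main plot title.
#' @return Invisibly, the bar midpoints.
#' @export
plot_profile96 <- function(catalog, main = "") {
  if (length(catalog) != 96) stop("catalog must have 96 channels")
  cols <- rep(c("#03BCEE", "#010101", "#E32926", "#CAC9C9", "#A1CE63",
                "#EBC6C4"), each = 16)
  mids <- graphics::barplot(as.numeric(catalog), col = cols, border = NA,
                            names.arg = rep("", 96), main = main,
                            ylab = "mutations")
  ctx <- channel_context()
  graphics::mtext(.SUBS, side = 1, at = mids[seq(8, 96, by = 16)], line = 1,
                  col = unique(cols), font = 2)
  invisible(mids)
}
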