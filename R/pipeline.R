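#' Run configuration with the standard reporting thresholds
#'
#' Defaults follow the conventional operating point: a variant/feature/
#' context record is flagged when |log-odds change| >= 1 and e-value <=
#' 0.05; LD groups use r-squared >= 0.8; context enumeration caps at 12
#' neighbours.
#'
#' @param L Window length.
#' @param background_n Background-null size.
#' @param background_seed Seed for the background sampler.
#' @param lo_threshold |log-odds change| flag threshold.
#' @param e_threshold e-value flag threshold.
#' @param ld_threshold LD-group r-squared threshold.
#' @param max_neighbors Context-enumeration cap.
#' @param stability_frac Context-stability fraction: a flagged variant/
#'   feature is labelled context-stable when its across-context range of
#'   log-odds change is below this fraction of its median absolute effect.
#' @param reversed_pass Also run the reverse-complement consistency check.
#' @return A `run_config` list.
#' @export
run_config <- function(L = 2000L, background_n = 999L,
                       background_seed = NULL, lo_threshold = 1,
                       e_threshold = 0.05, ld_threshold = 0.8,
                       max_neighbors = 12L, stability_frac = 0.25,
                       reversed_pass = FALSE) {
  structure(list(L = as.integer(L), background_n = as.integer(background_n),
                 background_seed = background_seed,
                 lo_threshold = lo_threshold, e_threshold = e_threshold,
                 ld_threshold = ld_threshold,
                 max_neighbors = as.integer(max_neighbors),
                 stability_frac = stability_frac,
                 reversed_pass = isTRUE(reversed_pass)),
            class = "run_config")
}

# windows around the scenario candidates, used to keep the desk-scale
# background sample clear of planted signal
candidate_windows <- function(spec, L) {
  spans <- lapply(spec$candidates, function(id) {
    v <- get_variant(spec$variants, id)
    sp <- window_span(v$pos, L)
    data.frame(chrom = v$chrom, start = sp$start, end = sp$end)
  })
  do.call(rbind, spans)
}

# rows of an effects table belonging to the all-major (no-context) context
no_context_records <- function(effects) {
  nb_part <- sub("^center=[a-z]+;?", "", effects$context_label)
  effects[!grepl("minor", nb_part, fixed = TRUE), , drop = FALSE]
}

#' Score every candidate of a scenario across its genetic contexts
#'
#' @param spec A `scenario_spec`.
#' @param genome,annotator,null Optional prebuilt stages (rebuilt from the
#'   scenario when NULL).
#' @param config A [run_config()].
#' @return List with `effects` (all contexts), `null`, `genome`,
#'   `annotator`.
#' @export
score_scenario <- function(spec, genome = NULL, annotator = NULL,
                           null = NULL, config = run_config()) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(genome)) genome <- make_genome(spec)
  if (is.null(annotator)) annotator <- make_annotator(spec)
  if (is.null(null)) {
    seed <- if (is.null(config$background_seed)) spec$seed + 11L
            else config$background_seed
    null <- build_background(genome, annotator, n = config$background_n,
                             seed = seed, L = config$L,
                             exclude = candidate_windows(spec, config$L))
  }
  effects <- do.call(rbind, lapply(spec$candidates, function(id) {
    center <- get_variant(spec$variants, id)
    nbs <- spec$variants[match(spec$neighbors[[id]], spec$variants$id), ,
                         drop = FALSE]
    score_variant(genome, center, nbs, annotator, null = null,
                  L = config$L, max_neighbors = config$max_neighbors)
  }))
  list(effects = effects, null = null, genome = genome,
       annotator = annotator)
}

#' Filter effects at the reporting thresholds and label context stability
#'
#' Rows passing both thresholds form the flagged table. For every flagged
#' variant/feature the across-context distribution of the log-odds change is
#' summarised and labelled `context_stable` when its range is below
#' `stability_frac` of the median absolute effect, else
#' `context_dependent` — an explicit operationalisation of "the effect does
#' not depend on the genetic context".
#'
#' @param effects Effect-record data.frame from [score_variant()] /
#'   [score_scenario()].
#' @param lo_threshold,e_threshold,stability_frac See [run_config()].
#' @return List with `flagged` (rows passing both thresholds) and `summary`
#'   (per flagged variant/feature: context distribution and label).
#' @export
report_flagged <- function(effects, lo_threshold = 1, e_threshold = 0.05,
                           stability_frac = 0.25) {
  pass <- abs(effects$log_odds_change) >= lo_threshold &
    !is.na(effects$e_value) & effects$e_value <= e_threshold
  flagged <- effects[pass, , drop = FALSE]
  if (!nrow(flagged)) {
    return(list(flagged = flagged,
                summary = data.frame(variant_id = character(0),
                                     feature = character(0))))
  }
  keys <- unique(flagged[, c("variant_id", "feature")])
  summ <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- effects[effects$variant_id == keys$variant_id[i] &
                     effects$feature == keys$feature[i], , drop = FALSE]
    loc <- sub$log_odds_change
    rng <- max(loc) - min(loc)
    med <- stats::median(abs(loc))
    data.frame(variant_id = keys$variant_id[i], feature = keys$feature[i],
               n_contexts = nrow(sub), min_loc = min(loc),
               median_loc = stats::median(loc), max_loc = max(loc),
               range = rng,
               label = if (rng < stability_frac * med) "context_stable"
                       else "context_dependent",
               stringsAsFactors = FALSE)
  }))
  list(flagged = flagged, summary = summ)
}

#' Across-context distribution summary per variant and feature
#'
#' @param effects Effect-record data.frame.
#' @return data.frame with per variant/feature min, median, max and range of
#'   the log-odds change over contexts.
#' @export
context_summary <- function(effects) {
  agg <- stats::aggregate(
    list(loc = effects$log_odds_change),
    by = list(variant_id = effects$variant_id, feature = effects$feature),
    FUN = function(x) c(n = length(x), min = min(x),
                        median = stats::median(x), max = max(x),
                        range = max(x) - min(x)))
  out <- cbind(agg[, 1:2], as.data.frame(agg$loc))
  names(out) <- c("variant_id", "feature", "n_contexts", "min_loc",
                  "median_loc", "max_loc", "range")
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run every stage of the analysis on a scenario
#'
#' Orchestrates background-null construction, context-aware effect scoring,
#' threshold reporting, LD-group contrasts and the cohort epistasis
#' validation, writing tab-delimited tables plus a run log under `outdir`.
#' A stage failure aborts with the stage name and leaves a `FAILED` marker
#' next to any partial outputs. Reruns with the same scenario and
#' configuration are identical.
#'
#' @param spec A `scenario_spec`.
#' @param outdir Output directory.
#' @param config A [run_config()].
#' @return Invisible list with all stage results.
#' @export
run_all <- function(spec, outdir, config = run_config()) {
  stopifnot(inherits(spec, "scenario_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  on.exit({
    writeLines(paste("failed at stage:", stage),
               file.path(outdir, "FAILED"))
  })
  res <- list()
  stage <- "scoring"
  scored <- score_scenario(spec, config = config)
  res$effects <- scored$effects
  write_tsv(res$effects, file.path(outdir, "effects.tsv"))
  bg <- data.frame(feature = rep(names(scored$null$estats),
                                 each = scored$null$n),
                   e_stat = unlist(scored$null$estats, use.names = FALSE))
  write_tsv(bg, file.path(outdir, "background_null.tsv"))

  stage <- "reporting"
  res$report <- report_flagged(res$effects, config$lo_threshold,
                               config$e_threshold, config$stability_frac)
  write_tsv(res$report$flagged, file.path(outdir, "flagged.tsv"))
  write_tsv(res$report$summary, file.path(outdir, "flagged_summary.tsv"))
  res$context_summary <- context_summary(res$effects)
  write_tsv(res$context_summary, file.path(outdir, "context_summary.tsv"))

  stage <- "reversed_pass"
  if (config$reversed_pass) {
    disc <- vapply(spec$candidates, function(id)
      max(reversed_check(scored$genome, get_variant(spec$variants, id),
                         annotator = scored$annotator, L = config$L)), 0)
    res$reversed_max_discrepancy <- max(disc)
    write_tsv(data.frame(variant_id = spec$candidates,
                         max_abs_discrepancy = unname(disc)),
              file.path(outdir, "reversed_check.tsv"))
  }

  stage <- "ld"
  hap <- make_haplotypes(spec)
  nc <- no_context_records(res$effects)
  anchors <- unique(res$report$flagged$variant_id)
  res$ld <- lapply(anchors, function(a) {
    grp <- suppressWarnings(correlated_group(hap, a, config$ld_threshold))
    grp$member_ids <- intersect(grp$member_ids, unique(nc$variant_id))
    grp$r2_to_anchor <- grp$r2_to_anchor[grp$member_ids]
    compare_group_effects(grp, nc, effect_threshold = config$lo_threshold)
  })
  names(res$ld) <- anchors
  ld_tab <- do.call(rbind, lapply(anchors, function(a)
    cbind(anchor_id = a, res$ld[[a]]$effects)))
  if (!is.null(ld_tab)) write_tsv(ld_tab, file.path(outdir, "ld_contrast.tsv"))

  stage <- "epistasis"
  gt <- make_cohort(spec)
  pair <- spec$cohort$pair
  res$carrier <- carrier_group_proportions(gt, pair[1], pair[2])
  res$epistasis <- epistasis_test(gt, pair[1], pair[2])
  write_tsv(res$carrier, file.path(outdir, "carrier_proportions.tsv"))
  write_tsv(data.frame(a = pair[1], b = pair[2],
                       statistic = res$epistasis$statistic,
                       p_value = res$epistasis$p_value,
                       method = res$epistasis$method),
            file.path(outdir, "epistasis.tsv"))

  stage <- "log"
  writeLines(c(
    sprintf("caism run, scenario seed %d", spec$seed),
    sprintf("window length L = %d", config$L),
    sprintf("background n = %d (seed %s)", config$background_n,
            if (is.null(config$background_seed)) spec$seed + 11L
            else config$background_seed),
    sprintf("thresholds: |log-odds change| >= %g, e <= %g",
            config$lo_threshold, config$e_threshold),
    sprintf("LD threshold r2 >= %g", config$ld_threshold),
    sprintf("max neighbors = %d", config$max_neighbors)),
    file.path(outdir, "run_log.txt"))
  on.exit()
  invisible(res)
}
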