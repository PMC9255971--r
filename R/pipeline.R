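#' End-to-end pipeline runner
#'
#' Runs the full medication-risk analysis on a cohort and writes the report
#' bundle: cohort summary, ATC class tallies, PIM prevalence, interaction
#' summary, network metrics per level (medication and ATC 1-3), chord matrices
#' and covariate association tables, plus a machine-readable manifest recording
#' the package version, seed, stages run or skipped, and the row count of every
#' output. Logs go to stderr; report files never interleave with logs. Any
#' stage failure aborts with the stage name.
#'
#' When `kb` is `NULL` the interaction, network and chord stages are skipped
#' and marked as such in the manifest; all other stages still run.
#'
#' @param cohort a `med_cohort`.
#' @param fml a `formulary`.
#' @param rules a `pim_ruleset`.
#' @param kb an `interaction_kb`, or `NULL` to skip interaction stages.
#' @param out_dir output directory (created if needed).
#' @param min_chord_count occurrence thresholds for the chord matrices, named
#'   `all` and `major` (the published diagrams hide level-2 pairs below 20 and
#'   major pairs below 3).
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @param association_vars covariate columns for the association tables.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(cohort, fml, rules, kb = NULL, out_dir,
                         min_chord_count = c(all = 20, major = 3),
                         seed = NULL,
                         association_vars = c("kps", "life_expectancy",
                                              "cancer_type", "gender")) {
  stopifnot(inherits(cohort, "med_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("polyrx")),
    seed = seed,
    n_patients = nrow(cohort$patients),
    stages = list(),
    outputs = list()
  )
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, code) {
    msg <- tryCatch({
      res <- code
      manifest$stages[[name]] <<- "ok"
      message(sprintf("[%s] done (%.1fs)", name,
                      proc.time()[["elapsed"]] - t0))
      res
    }, error = function(e) {
      stop_("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    msg
  }
  record <- function(file, n_rows) {
    manifest$outputs[[file]] <<- n_rows
  }
  out <- function(file) file.path(out_dir, file)

  summ <- stage("cohort_summary", {
    s <- cohort_summary(cohort)
    jsonlite::write_json(unclass(s), out("cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    record("cohort_summary.json", 1L)
    s
  })

  annotation <- stage("classify", {
    ann <- classify_cohort(cohort, fml)
    tally <- atc_tally(ann, level = 2)
    utils::write.csv(tally, out("atc_level2_tally.csv"), row.names = FALSE,
                     quote = FALSE)
    record("atc_level2_tally.csv", nrow(tally))
    utils::write.csv(ann$unclassified, out("unclassified.csv"),
                     row.names = FALSE, quote = FALSE)
    record("unclassified.csv", nrow(ann$unclassified))
    ann
  })

  stage("screen", {
    flags <- screen_cohort(cohort, rules, annotation)
    utils::write.csv(flags, out("pim_flags.csv"), row.names = FALSE,
                     quote = FALSE)
    record("pim_flags.csv", nrow(flags))
    prev <- pim_prevalence(cohort, flags)
    jsonlite::write_json(
      list(pct_beers = prev$pct_beers, pct_stopp = prev$pct_stopp,
           pct_union = prev$pct_union,
           pct_nonrx_flags = as.list(prev$pct_nonrx_flags)),
      out("pim_prevalence.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    record("pim_prevalence.json", 1L)
    prev
  })

  if (is.null(kb)) {
    for (nm in c("interact", "network", "chord")) {
      manifest$stages[[nm]] <- "skipped (no knowledge base)"
    }
    message("[interact/network/chord] skipped: no knowledge base")
  } else {
    detections <- stage("interact", {
      d <- detect_interactions(cohort, kb)
      utils::write.csv(d, out("interactions.csv"), row.names = FALSE,
                       quote = FALSE)
      record("interactions.csv", nrow(d))
      s <- interaction_summary(cohort, d)
      jsonlite::write_json(unclass(s), out("interaction_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      record("interaction_summary.json", 1L)
      d
    })
    ddi <- detections[detections$kind == "DDI", , drop = FALSE]

    stage("network", {
      metrics <- lapply(list(medication = "medication", atc1 = 1, atc2 = 2,
                             atc3 = 3), function(lvl) {
        unclass(compute_metrics(build_network(ddi, lvl, annotation)))
      })
      jsonlite::write_json(metrics, out("network_metrics.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      record("network_metrics.json", length(metrics))
      net2 <- build_network(ddi, 2, annotation)
      write_edge_list(net2, out("edges_level2.csv"))
      record("edges_level2.csv", nrow(net2$edges))
      NULL
    })

    stage("chord", {
      m_all <- chord_matrix(ddi, 2, annotation,
                            min_count = min_chord_count[["all"]])
      write_chord_matrix(m_all, out("chord_level2_all.csv"))
      record("chord_level2_all.csv", nrow(m_all))
      major <- ddi[ddi$major, , drop = FALSE]
      m_major <- chord_matrix(major, 2, annotation,
                              min_count = min_chord_count[["major"]])
      write_chord_matrix(m_major, out("chord_level2_major.csv"))
      record("chord_level2_major.csv", nrow(m_major))
      NULL
    })
  }

  stage("associate", {
    counts <- regular_med_count(cohort)
    poly <- counts$n_regular >= 5
    vars <- intersect(association_vars, names(cohort$patients))
    tabs <- lapply(vars, function(v) {
      tab <- association_table(cohort$patients[[v]], poly)
      cbind(variable = v, tab)
    })
    assoc <- do.call(rbind, tabs)
    utils::write.csv(assoc, out("association_polypharmacy.csv"),
                     row.names = FALSE, quote = FALSE)
    record("association_polypharmacy.csv", nrow(assoc))
    NULL
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
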