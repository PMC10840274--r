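#' Pipeline run configuration
#'
#' Collects paths and parameters for a full run. Either `simulate = TRUE`
#' (a synthetic cohort is generated under `outdir` first) or the four
#' input paths must point at existing files. Referenced inputs are
#' validated before any stage executes.
#'
#' @param outdir output directory.
#' @param simulate generate the cohort with [simulate_cohort()] first.
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param counts,gene_cn,gmt,groups input paths (ignored when simulating).
#' @param cn_drivers,mut_drivers optional driver-list paths (one gene id
#'   per line) enabling the landscape stage on real inputs.
#' @param family,k_max model options, see [gene_cni()].
#' @param mean_cna_mode see [mean_cna()].
#' @param q_threshold FDR threshold for group enrichment.
#' @param resamples landscape resampling rounds.
#' @param seed master seed recorded in every output header.
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir, simulate = FALSE, sim = sim_config(),
                       counts = NULL, gene_cn = NULL, gmt = NULL,
                       groups = NULL, cn_drivers = NULL, mut_drivers = NULL,
                       family = "monotonic", k_max = 8L,
                       mean_cna_mode = "total", q_threshold = 0.05,
                       resamples = 1000L, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  if (!simulate) {
    for (f in c("counts", "gene_cn", "gmt")) {
      check(!is.null(cfg[[f]]), "run_config: '%s' path required", f)
    }
    for (f in c("counts", "gene_cn", "gmt", "groups", "cn_drivers",
                "mut_drivers")) {
      if (!is.null(cfg[[f]])) {
        check(file.exists(cfg[[f]]), "input not found: %s", cfg[[f]])
      }
    }
  }
  cfg
}

read_gene_list <- function(path) {
  v <- trimws(readLines(path, warn = FALSE))
  v[nzchar(v)]
}

#' Run the full CNI pipeline
#'
#' Executes the stages in dependency order — (simulate) -> align -> gene
#' CNI -> pathway CNI -> transitions -> (stacked group models ->
#' enrichment) -> (landscape) — writing TSV outputs with a provenance
#' header and a JSON manifest of MD5 hashes. A stage failure aborts with
#' the stage named. No stage mutates its inputs; rerunning an identical
#' config reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config) {
  check(inherits(config, "run_config"), "config must come from run_config()")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  prov <- sprintf("cnimpact %s seed=%d",
                  as.character(utils::packageVersion("cnimpact")),
                  config$seed)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$outdir, name)
    con <- file(path, "w")
    writeLines(paste0("# ", prov), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    written <<- c(written, path)
    path
  }

  if (config$simulate) {
    cohort <- stage("simulate", {
      sim <- config$sim
      sim$seed <- config$seed
      simulate_cohort(sim, outdir = file.path(config$outdir, "cohort"))
    })
    expr <- cohort$expr
    cn <- cohort$cn
    pathways <- cohort$pathways
    groups <- cohort$groups
    cn_drivers <- cohort$truth$cn_drivers
    mut_drivers <- cohort$truth$mut_drivers
    written <- c(written, file.path(config$outdir, "cohort",
                                    c("counts.tsv", "gene_cn.tsv",
                                      "pathways.gmt", "groups.tsv",
                                      "truth.tsv")))
  } else {
    expr <- stage("read_counts", read_counts(config$counts))
    cn <- stage("read_gene_cn", read_gene_cn(config$gene_cn))
    pathways <- stage("read_gmt", read_gmt(config$gmt))
    groups <- if (is.null(config$groups)) NULL else {
      stage("read_groups", read_groups(config$groups))
    }
    cn_drivers <- if (is.null(config$cn_drivers)) NULL else {
      stage("read_drivers", read_gene_list(config$cn_drivers))
    }
    mut_drivers <- if (is.null(config$mut_drivers)) NULL else {
      stage("read_drivers", read_gene_list(config$mut_drivers))
    }
  }

  al <- stage("align", align(expr, cn))
  expr <- al$expr
  cn <- al$cn
  g <- stage("scales", estimate_sample_scales(expr))

  gene_stats <- stage("gene_cni", cni_table(expr, cn, g,
                                            family = config$family,
                                            k_max = config$k_max))
  emit(gene_stats, "gene_cni.tsv")

  pw_stats <- stage("pathway_cni",
                    pathway_cni_table(gene_stats, pathways, cn = cn,
                                      mean_cna_mode = config$mean_cna_mode))
  emit(pw_stats, "pathway_cni.tsv")

  trans <- stage("transition", transition_table(expr, cn, g,
                                                k_max = config$k_max))
  emit(trans, "transitions.tsv")

  if (!is.null(groups)) {
    stacked <- stage("stacked", stacked_cni_table(expr, cn, groups, g,
                                                  k_max = config$k_max))
    emit(stacked, "stacked_cni.tsv")
    enr <- stage("enrichment", group_enrichment(stacked, pathways,
                                                config$q_threshold))
    emit(enr, "enrichment.tsv")
  }

  if (!is.null(cn_drivers) && !is.null(mut_drivers)) {
    landscape <- stage("landscape", {
      ref <- build_reference_distributions(gene_stats, pathways, cn_drivers,
                                           mut_drivers, cn,
                                           n_resamples = config$resamples,
                                           seed = config$seed,
                                           mean_cna_mode = config$mean_cna_mode)
      thr <- calibrate_landscape(ref)
      cls <- classify_quadrants(pw_stats, thr)
      attr(cls, "thresholds") <- thr
      cls
    })
    thr <- attr(landscape, "thresholds")
    emit(landscape, "landscape.tsv")
    emit(data.frame(axis = c("cni", "cna"),
                    threshold = c(thr$cni_threshold, thr$cna_threshold),
                    accuracy = c(thr$accuracy_cni, thr$accuracy_cna)),
         "thresholds.tsv")
  }

  manifest <- list(tool = "cnimpact",
                   version = as.character(utils::packageVersion("cnimpact")),
                   seed = config$seed,
                   files = as.list(tools::md5sum(written[file.exists(written)])))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
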