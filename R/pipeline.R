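#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or read) -> preprocess -> classify -> motifs ->
#' enrichment -> template match -> cluster and writes a deterministic result
#' bundle: `calls.tsv`, `timing_groups.tsv`, `divergent.tsv`,
#' `motifcalls.tsv`, `enrichment.tsv`, `template_hits.tsv`, `clusters.tsv`
#' and `summary.json` (category counts, imputed fraction, filter
#' bookkeeping), plus `manifest.json` echoing the seed and parameters.
#' Re-running with the same config reproduces the bundle byte for byte.
#'
#' @param config a named list or path to a YAML file. Recognized entries:
#'   `out_dir` (required), `input` (path to a native site table; if absent a
#'   dataset is simulated), `sim` (arguments to [simConfig()]), `dynamics`
#'   (arguments to [dynamicsConfig()]), `smooth` (default TRUE),
#'   `smooth_mode`, `p_threshold` (default 0.01), `template` (optional
#'   list for [templateMatch()]), `template_k` (default 29), `n_top`
#'   (default 40), `n_subtrees` (default 12), `divergent_mode`.
#' @return invisibly, a list with the in-memory results.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config))
            stop("config file does not exist: ", config)
        config <- yaml::read_yaml(config)
    }
    if (is.null(config$out_dir)) stop("config must name an out_dir")
    for (p in config$input)
        if (!file.exists(p)) stop("input path does not exist: ", p)

    cfg_dyn <- do.call(dynamicsConfig, config$dynamics %||% list())
    truth <- NULL
    if (!is.null(config$input)) {
        sites <- readSiteTable(config$input)
    } else {
        sim <- do.call(simConfig, config$sim %||% list())
        gen <- generateDataset(sim, cfg_dyn)
        sites <- gen$sites
        truth <- gen$truth
    }
    message("loaded ", nrow(sites), " sites")

    pre <- preprocessPhospho(sites, cfg_dyn,
                             smooth = config$smooth %||% TRUE,
                             smooth_mode = config$smooth_mode %||% "paper")
    prof <- pre$profiles
    message("retained ", nrow(prof), " sites after filtering (",
            nrow(pre$rejects), " rejected); imputed fraction ",
            round(imputedFraction(prof), 3))

    calls_c <- classifyProfiles(prof, cfg_dyn, "ctrl")
    calls_m <- classifyProfiles(prof, cfg_dyn, "mut")
    calls <- rbind(calls_c, calls_m)

    tg <- timingGroups(calls_c, prof)
    tg_df <- if (length(tg)) {
        do.call(rbind, lapply(names(tg), function(nm)
            data.frame(timing_min = as.numeric(nm), n = tg[[nm]]$n,
                       t(tg[[nm]]$mean_profile))))
    } else data.frame()

    mode <- config$divergent_mode %||% "dephos_ctrl_stable_mut"
    div <- selectDivergent(calls_c, calls_m, prof, mode)
    top <- rankAffected(div, min(config$n_top %||% 40L, max(nrow(div), 1L)))

    mot <- annotateMotifs(prof)

    fg_keys <- calls_c$category == "dephosphorylated"
    enr <- if (any(fg_keys)) {
        icelogoEnrich(siteWindows(prof)[fg_keys], siteWindows(prof),
                      config$p_threshold %||% 0.01)
    } else data.frame()

    hits <- if (!is.null(config$template)) {
        templateMatch(prof, config$template, config$template_k %||% 29L)
    } else data.frame()

    ncl <- config$n_subtrees %||% 12L
    clu <- if (nrow(prof) >= ncl) hierCluster(prof, ncl) else NULL
    clu_df <- if (is.null(clu)) data.frame() else
        data.frame(site_key = names(clu$labels), cluster = clu$labels,
                   row.names = NULL)

    out_dir <- config$out_dir
    paths <- tryCatch(
        writeResults(list(calls = calls, timing_groups = tg_df,
                          divergent = top, motifcalls = mot,
                          enrichment = enr, template_hits = hits,
                          clusters = clu_df), out_dir),
        error = function(e) {
            unlink(file.path(out_dir, paste0(
                c("calls", "timing_groups", "divergent", "motifcalls",
                  "enrichment", "template_hits", "clusters"), ".tsv")))
            stop("writing results failed: ", conditionMessage(e))
        })

    summary <- list(
        n_input = nrow(sites), n_retained = nrow(prof),
        n_rejected = nrow(pre$rejects),
        imputed_fraction = imputedFraction(prof),
        category_counts_ctrl = as.list(table(calls_c$category)),
        category_counts_mut = as.list(table(calls_m$category)),
        n_divergent = nrow(div))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(package_version = as.character(
                         utils::packageVersion("mitophos")),
                     config = config[setdiff(names(config), "template")])
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(sites = sites, truth = truth, profiles = prof,
                   rejects = pre$rejects, calls_ctrl = calls_c,
                   calls_mut = calls_m, timing_groups = tg,
                   divergent = div, top_affected = top, motifs = mot,
                   enrichment = enr, template_hits = hits, clusters = clu,
                   summary = summary, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
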