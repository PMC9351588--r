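#' Run the full network-reconstruction pipeline from a config
#'
#' Chains power-law fitting, optional functional clustering, partner
#' selection, qdODE fitting, network assembly and (when context labels are
#' present) the permutation LR test, writing all tables, graphs and a
#' manifest of file hashes into a run directory. Outputs are a pure
#' function of (inputs, config, seed): re-running with the same config
#' reproduces identical file hashes. Timestamps go only to the log file,
#' which is excluded from the manifest.
#'
#' @param config a list, or the path of a YAML file, with entries:
#'   \describe{
#'     \item{input}{list with `abundance` (TSV path) and optional
#'       `metadata` path, or}
#'     \item{simulate}{list with `scenario` name and `seed`}
#'     \item{order}{LOP degree (default 3)}
#'     \item{nlambda}{selection grid size (default 50)}
#'     \item{epsilon}{neutrality threshold (default per-edge rule)}
#'     \item{weights, predictor}{stage options (see [build_design()])}
#'     \item{cluster}{optional list with `L_max` to run module detection}
#'     \item{compare}{optional list with `n_perm` and `seed` for the
#'       context test}
#'     \item{seed}{global seed (default 1)}
#'   }
#' @param outdir run directory (created; must be empty or absent)
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(order = 3, nlambda = 50, epsilon = NULL,
                                weights = "parabolic",
                                predictor = "smoothed", seed = 1),
                           config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  say <- function(fmt, ...) cat(sprintf("[%s] %s\n", format(Sys.time()),
                                        sprintf(fmt, ...)),
                                file = logf, append = TRUE)
  stage <- function(name, expr) {
    say("stage %s: start", name)
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say("stage %s: done", name)
    r
  }
  outputs <- character(0)
  emit <- function(obj, name) {
    p <- file.path(outdir, name)
    utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }

  M <- stage("load", {
    if (!is.null(cfg$simulate)) {
      sim <- generate_abundance(scenario(cfg$simulate$scenario,
                                         seed = cfg$simulate$seed %||% cfg$seed))
      p <- file.path(outdir, "abundance.tsv")
      write_abundance(sim$abund, p)
      outputs <- c(outputs, p)
      sim$abund
    } else {
      read_abundance(cfg$input$abundance, metadata = cfg$input$metadata)
    }
  })
  pf <- stage("fit-power", fit_power_all(M))
  emit(as.data.frame(pf), "power_fits.tsv")

  if (!is.null(cfg$cluster)) {
    cl <- stage("cluster", select_L(M, L_max = cfg$cluster$L_max %||% 6,
                                    seed = cfg$seed))
    emit(data.frame(taxon = names(cl$labels), module = cl$labels,
                    posterior_max = apply(cl$posterior, 1, max)),
         "modules.tsv")
    emit(cl$module_params, "module_params.tsv")
    emit(cl$bic_path, "bic_path.tsv")
  }

  links <- stage("select",
                 select_links(M, order = cfg$order, fits = pf,
                              predictor = cfg$predictor,
                              weights = cfg$weights,
                              nlambda = cfg$nlambda))
  emit(do.call(rbind, lapply(links, function(s) {
    if (!length(s$selected)) return(NULL)
    data.frame(focal = s$focal, partner = s$selected,
               group_norm = s$group_norms[s$selected],
               rank = seq_along(s$selected), row.names = NULL)
  })) %||% data.frame(focal = character(), partner = character(),
                      group_norm = numeric(), rank = integer()),
  "links.tsv")

  ode <- stage("fit", fit_qdode(M, links, order = cfg$order, fits = pf,
                                weights = cfg$weights))
  emit(do.call(rbind, lapply(ode, function(f)
    cbind(taxon = f$focal, decompose(f)[, c("sample", "H", "observed",
                                            "fitted", "independent",
                                            "dependent_pos",
                                            "dependent_neg")]))),
    "trajectories.tsv")
  emit(data.frame(taxon = names(ode),
                  rss = vapply(ode, function(f) f$rss, 0),
                  sigma2 = vapply(ode, function(f) f$sigma2, 0),
                  converged = vapply(ode, function(f) f$converged, TRUE)),
       "fit_summary.tsv")

  net <- stage("network", build_network(ode, epsilon = cfg$epsilon))
  gml <- file.path(outdir, "network.graphml")
  write_network(net, graphml = gml,
                edges = file.path(outdir, "edges.tsv"))
  outputs <- c(outputs, gml, file.path(outdir, "edges.tsv"))
  emit(classify_roles(net), "roles.tsv")
  emit(classify_all_pairs(net), "pairs.tsv")

  if (!is.null(cfg$compare)) {
    if (is.null(M$context)) {
      warning("no context labels available; compare stage skipped")
      say("stage compare: skipped (no context labels)")
    } else {
      ct <- stage("compare",
                  permutation_test(M, n_perm = cfg$compare$n_perm %||% 1000,
                                   seed = cfg$compare$seed %||% cfg$seed,
                                   order = cfg$order, fits = pf,
                                   links = links, weights = cfg$weights))
      jsonlite::write_json(list(lr = ct$lr, threshold95 = ct$threshold95,
                                pvalue = ct$pvalue, n_perm = ct$n_perm,
                                seed = ct$seed),
                           file.path(outdir, "context_test.json"),
                           auto_unbox = TRUE, digits = NA)
      emit(data.frame(perm = seq_along(ct$null_lrs), lr = ct$null_lrs),
           "null_lrs.tsv")
      outputs <- c(outputs, file.path(outdir, "context_test.json"))
    }
  }

  manifest <- list(package = "qdnet",
                   version = as.character(utils::packageVersion("qdnet")),
                   seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "input")],
                   files = lapply(stats::setNames(outputs, basename(outputs)),
                                  function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: %d output files", length(outputs))
  invisible(manifest)
}
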