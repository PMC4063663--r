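#' @title End-to-end pipeline
#' @description
#' Orchestrates synth/read -> classify -> build -> fold -> analyze ->
#' mechanism -> nsd from a single YAML configuration with explicit seeds, so
#' a full study is reproducible from one file. Each stage's failure is
#' reported with the stage name and the config hash.
#' @name pipeline
NULL

default_config <- function() {
  list(
    seed = 1,
    bundle = list(kind = "pierced_C", helix_length = 14, loop_length = 5,
                  jitter = 0),
    input = NULL,   # list(path=, chain=, model=) to read a PDB instead
    states = c("oxidized", "reduced"),
    model = list(cutoff = 8.0, min_seq_sep = 4, lambda = 1.2,
                 width = 0.05, eps_ss = 1.0),
    fold = list(enabled = TRUE, temperatures = c(0.65, 0.75, 0.85, 0.95),
                n_steps = 2e5, stride = 100),
    mechanism = list(enabled = FALSE, n_runs = 20, temperature = 0.7,
                     n_steps = 3e5, stride = 200),
    nsd = list(enabled = FALSE, t_frac = 0.7, n_steps = 2e5, stride = 50,
               n_blocks = 10)
  )
}

#' Read / write a pipeline configuration
#'
#' YAML key/value config; unspecified keys take defaults. The config
#' round-trips through serialization unchanged.
#'
#' @param path YAML file.
#' @return nested list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), raw)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @param cfg a config list.
#' @export
write_pipeline_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]   # canonical form: no nulls
  yaml::write_yaml(cfg, path)
  invisible(path)
}

validate_pipeline_config <- function(cfg) {
  known <- names(default_config())
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  }
  if (!is.numeric(cfg$seed)) stop("config key 'seed' must be numeric")
  bad_state <- setdiff(cfg$states, c("oxidized", "reduced", "dynamic"))
  if (length(bad_state) > 0) {
    stop("unknown disulphide state in config: ", paste(bad_state, collapse = ", "))
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' @param config a `pipeline_config`, a path to one, or `NULL` for the
#'   built-in demo configuration.
#' @param out_dir optional directory for stage outputs (classification TSV,
#'   Cv grids, summary JSON); nothing is written when `NULL`.
#' @return a list (invisibly if `out_dir` given): `structure`,
#'   `classification`, `topologies`, `thermo` (per state), `mechanism`,
#'   `nsd`, `summary`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- if (is.null(config)) {
    structure(default_config(), class = "pipeline_config")
  } else if (is.character(config)) {
    read_pipeline_config(config)
  } else {
    cfg0 <- utils::modifyList(default_config(), unclass(config))
    validate_pipeline_config(cfg0)
    structure(cfg0, class = "pipeline_config")
  }
  cfg_id <- sprintf("%08x", sum(utf8ToInt(paste(deparse(unclass(cfg)),
                                                collapse = ""))))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed [config ", cfg_id, "]: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  s <- stage("input", {
    if (!is.null(cfg$input)) {
      read_structure(cfg$input$path, cfg$input$chain,
                     cfg$input$model %||% 1)
    } else {
      make_bundle(cfg$bundle$kind, cfg$bundle$helix_length,
                  cfg$bundle$loop_length, seed = cfg$seed,
                  jitter = cfg$bundle$jitter %||% 0)
    }
  })
  classification <- stage("classify", classify_lasso(s))
  bridge <- if (nrow(classification) > 0) {
    c(classification$i[1], classification$j[1])
  } else {
    NULL
  }

  cm <- stage("build", build_contact_map(s, cutoff = cfg$model$cutoff,
                                         min_seq_sep = cfg$model$min_seq_sep))
  topologies <- stage("build", {
    st <- stats::setNames(cfg$states, cfg$states)
    lapply(st, function(state) {
      build_topology(s, cm, bridge, state = state,
                     eps_ss = cfg$model$eps_ss, width = cfg$model$width)
    })
  })

  thermo <- NULL
  if (isTRUE(cfg$fold$enabled)) {
    thermo <- stage("fold", {
      lapply(topologies, function(tp) {
        runs <- lapply(seq_along(cfg$fold$temperatures), function(k) {
          c2 <- run_config(temperature = cfg$fold$temperatures[k],
                           n_steps = cfg$fold$n_steps,
                           stride = cfg$fold$stride,
                           seed = cfg$seed * 1000 + k)
          run_langevin(tp, tp$x_native, c2)
        })
        wham_cv(lapply(runs, function(r) r$e_pot), cfg$fold$temperatures)
      })
    })
  }

  mech <- NULL
  if (isTRUE(cfg$mechanism$enabled) && !is.null(bridge) &&
      classification$label[1] == "pierced_lasso") {
    mech <- stage("mechanism", {
      tp <- topologies[[if ("oxidized" %in% names(topologies)) "oxidized" else 1]]
      recs <- thread_mechanism_ensemble(
        tp, s, bridge, n_runs = cfg$mechanism$n_runs,
        temperature = cfg$mechanism$temperature,
        n_steps = cfg$mechanism$n_steps, stride = cfg$mechanism$stride,
        seed = cfg$seed * 100)
      if (nrow(recs) > 0) mechanism_stats(recs) else NULL
    })
  }

  nsd_out <- NULL
  if (isTRUE(cfg$nsd$enabled) && !is.null(bridge) && !is.null(thermo) &&
      all(c("oxidized", "reduced") %in% names(topologies))) {
    nsd_out <- stage("nsd", {
      profs <- lapply(c("reduced", "oxidized"), function(state) {
        tr <- sample_native(topologies[[state]], tf = thermo[[state]]$Tf,
                            t_frac = cfg$nsd$t_frac,
                            n_steps = cfg$nsd$n_steps,
                            stride = cfg$nsd$stride, seed = cfg$seed * 10)
        pca_fluctuations(tr, n_blocks = cfg$nsd$n_blocks)
      })
      d <- nsd_difference(profs[[1]], profs[[2]], bridge)
      pt <- nsd_permutation_test(profs[[1]], profs[[2]], bridge,
                                 seed = cfg$seed)
      list(difference = d, permutation = pt)
    })
  }

  summary <- list(
    config_id = cfg_id,
    n_residues = nrow(s),
    classification = as.list(classification[1, ,
                                            drop = FALSE])[
      c("label", "terminus", "loop_size")],
    Tf = if (!is.null(thermo)) lapply(thermo, function(t) t$Tf) else NULL,
    mechanism = if (!is.null(mech)) {
      stats::setNames(as.list(mech$fraction), mech$label)
    } else NULL,
    nsd = if (!is.null(nsd_out)) {
      c(as.list(attr(nsd_out$difference, "summary")),
        p_distal = nsd_out$permutation$p_value)
    } else NULL
  )

  res <- list(structure = s, classification = classification,
              topologies = topologies, thermo = thermo, mechanism = mech,
              nsd = nsd_out, summary = summary, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(classification, file.path(out_dir, "classification.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(thermo)) {
      for (nm in names(thermo)) {
        utils::write.table(thermo[[nm]]$cv,
                           file.path(out_dir, paste0("cv_", nm, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
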