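# Pipeline orchestration: run configured stages and aggregate one report.

PIPELINE_KEYS <- c("structure", "classify", "phylo", "thermal", "chemical",
                   "compare", "output_dir", "seed")

#' Read a denaturation curve from CSV
#'
#' Accepts a header of either \code{temperature_C,signal} (thermal) or
#' \code{conc_M,signal} (chemical).
#'
#' @param path CSV file path.
#' @return a \code{melting_curve} or a chemical-curve data frame.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  df <- read.csv(path)
  if (any(c("temperature_C", "temp_C") %in% names(df))) {
    as_melting_curve(df)
  } else if ("conc_M" %in% names(df)) {
    df
  } else {
    stop("unrecognized curve header in ", path,
         " (expected temperature_C,signal or conc_M,signal)")
  }
}

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  paths <- c(cfg$structure$path, cfg$classify$msa,
             vapply(cfg$thermal, function(x) x$path %||% NA_character_,
                    character(1)),
             vapply(cfg$chemical, function(x) x$path %||% NA_character_,
                    character(1)))
  paths <- paths[!is.na(paths)]
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the configured analysis pipeline
#'
#' Executes, as configured: salt-bridge detection plus SASA burial on a
#' structure; hallmark profiling and subfamily classification on an
#' alignment; a Poisson-corrected neighbor-joining tree; two-state fits of
#' thermal and chemical denaturation curves; and a variant-comparison table
#' (dTm, ddG). Writes \code{report.json} (and \code{tree.nwk} when a
#' phylogeny is computed) into \code{output_dir} and returns the report.
#'
#' Config layout (YAML file or list): \describe{
#'   \item{structure}{\code{path}, optional \code{cutoff},
#'     \code{include_his}, \code{probe}, \code{n_points}.}
#'   \item{classify}{\code{msa} (path), \code{reference_id},
#'     \code{target_ids}, \code{triads} (named list of \code{c(ser, asp,
#'     his)}), optional \code{cap_labels}.}
#'   \item{phylo}{logical: build an NJ tree from the classify alignment.}
#'   \item{thermal}{list of \code{name}, \code{path} entries.}
#'   \item{chemical}{list of \code{name}, \code{path} entries.}
#'   \item{compare}{\code{ref}, \code{mut} (names of thermal fits),
#'     optional \code{temp_C}.}
#'   \item{output_dir}{report directory (default \code{"."}).}
#' }
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @return the report, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(schema = "bridgestab-report/1", stages = list())
  t_all <- Sys.time()

  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] running ...", name))
    value <- expr()
    report$stages[[name]] <<- c(value, list(
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    invisible()
  }

  ok <- tryCatch({
    if (!is.null(config$structure)) {
      run_stage("bridges", function() {
        sc <- config$structure
        s <- read_structure(sc$path)
        br <- detect_salt_bridges(s, cutoff = sc$cutoff %||% 4.0,
                                  include_his = sc$include_his %||% TRUE)
        sasa <- compute_sasa(s, probe = sc$probe %||% 1.4,
                             n_points = sc$n_points %||% 960)
        br <- bridge_burial(sasa, br)
        list(structure_id = s$id, n_bridges = nrow(br),
             bridges = as.data.frame(br), total_sasa_A2 = sasa$total_A2)
      })
    }
    if (!is.null(config$classify)) {
      run_stage("classify", function() {
        cc <- config$classify
        m <- read_msa(cc$msa)
        cat_ <- hallmark_catalog()
        calls <- lapply(cc$target_ids, function(id) {
          pnp <- hallmark_profile(m, id, cat_$nprime_exclusive,
                                  cc$reference_id)
          triad <- cc$triads[[id]]
          ungapped <- gsub("-", "", msa_row(m, id))
          il <- interloop_bridge(ungapped, triad = unlist(triad))
          cap <- (cc$cap_labels[[id]]) %||% "unknown"
          call <- classify_subfamily(pnp, NULL, il, cap_label = cap)
          list(id = id, label = call$label, notes = call$notes)
        })
        list(calls = calls)
      })
    }
    if (isTRUE(config$phylo)) {
      run_stage("phylo", function() {
        m <- read_msa(config$classify$msa)
        dm <- poisson_distance(m)
        tree <- nj_tree(dm)
        nwk <- file.path(out_dir, "tree.nwk")
        ape::write.tree(tree, file = nwk)
        list(n_taxa = length(tree$tip.label), newick = nwk,
             distances = dm$d)
      })
    }
    fits <- list()
    if (!is.null(config$thermal)) {
      run_stage("thermal", function() {
        res <- lapply(config$thermal, function(entry) {
          fit <- linearized_stability(read_curve(entry$path))$fit
          fits[[entry$name]] <<- fit
          list(name = entry$name, Tm_C = fit$Tm_C,
               dHm_kcal_mol = fit$dHm_kcal_mol, rss = fit$rss)
        })
        list(fits = res)
      })
    }
    if (!is.null(config$chemical)) {
      run_stage("chemical", function() {
        res <- lapply(config$chemical, function(entry) {
          fit <- chem_midpoint(read_curve(entry$path))
          list(name = entry$name, Cm_M = fit$Cm_M,
               m_kcal_mol_M = fit$m_kcal_mol_M)
        })
        list(fits = res)
      })
    }
    if (!is.null(config$compare)) {
      run_stage("compare", function() {
        cmp <- config$compare
        if (is.null(fits[[cmp$ref]]) || is.null(fits[[cmp$mut]])) {
          stop("compare refers to unknown thermal fits: ",
               cmp$ref, ", ", cmp$mut)
        }
        compare_variants(fits[[cmp$ref]], fits[[cmp$mut]],
                         temp_C = cmp$temp_C %||% 25)
      })
    }
    TRUE
  }, error = function(e) {
    report$errors <<- conditionMessage(e)
    FALSE
  })

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (!ok) {
    stop("pipeline failed: ", report$errors, " (partial report written to ",
         file.path(out_dir, "report.json"), ")")
  }
  invisible(report)
}
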