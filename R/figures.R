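#' Run the multi-trait prediction analysis
#'
#' Computes one prediction curve per trait (diseases on the fold-change
#' scale, quantitative traits in phenotypic s.d.) for m = 1..max_m edited
#' loci, writes one tidy CSV per trait plus a JSON run manifest, and returns
#' the curves invisibly. Traits that fail are logged and skipped; if any
#' fail the function raises an error after processing the rest.
#'
#' @param inputs Named list, one element per trait, each a list with
#'   \code{trait} (a [trait_config()]) and \code{path} (a locus TSV), as
#'   returned by [make_disease_fixture()].
#' @param out_dir Output directory (created if needed).
#' @param max_m Maximum number of edited loci (default 10).
#' @param rg Genetic correlation with the future environment (default 1).
#' @param col_map Optional column mapping passed to [read_locus_table()].
#' @return Invisibly, a named list of \code{prediction_curve} data frames.
#' @export
run_figure1 <- function(inputs, out_dir, max_m = 10L, rg = 1,
                        col_map = NULL) {
  stopifnot(length(inputs) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  curves <- list()
  failures <- character(0)
  for (nm in names(inputs)) {
    res <- tryCatch({
      curve <- prediction_curve_for(inputs[[nm]], max_m = max_m, rg = rg,
                                    col_map = col_map)
      out_path <- file.path(out_dir, paste0("curve_", tolower(nm), ".csv"))
      utils::write.csv(curve, out_path, row.names = FALSE)
      curve
    }, error = function(e) {
      message("trait ", nm, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- c(failures, nm) else curves[[nm]] <- res
  }
  write_manifest(out_dir, inputs,
                 params = list(max_m = max_m, rg = rg),
                 failures = failures)
  if (length(failures)) {
    stop("failed traits: ", paste(failures, collapse = ", "))
  }
  invisible(curves)
}

prediction_curve_for <- function(input, max_m, rg, col_map = NULL) {
  records <- read_locus_table(input$path, input$trait, col_map = col_map)
  oriented <- rank_loci(orient_loci(records, input$trait), max_m = max_m)
  plan <- edit_plan(input$trait, oriented, max_m = max_m, rg = rg)
  if (input$trait$kind == "binary") disease_curve(plan) else
    quantitative_curve(plan)
}

#' Run the gene-by-environment attenuation analysis
#'
#' As [run_figure1()], but over a grid of genetic correlations \code{rg};
#' the output is one tidy CSV per trait with an \code{rg} column, so each
#' trait's file holds \code{length(rg_grid)} stacked curves. \code{rg = 1}
#' rows reproduce [run_figure1()] exactly; \code{rg = 0} rows are flat at
#' the unedited baseline.
#'
#' @inheritParams run_figure1
#' @param rg_grid Numeric vector of genetic correlations in [0, 1].
#' @return Invisibly, a named list of stacked \code{prediction_curve} data
#'   frames.
#' @export
run_figure2 <- function(inputs, out_dir, max_m = 10L,
                        rg_grid = seq(0, 1, by = 0.25), col_map = NULL) {
  stopifnot(all(rg_grid >= 0 & rg_grid <= 1))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  curves <- list()
  failures <- character(0)
  for (nm in names(inputs)) {
    res <- tryCatch({
      stacked <- do.call(rbind, lapply(rg_grid, function(r) {
        prediction_curve_for(inputs[[nm]], max_m = max_m, rg = r,
                             col_map = col_map)
      }))
      out_path <- file.path(out_dir, paste0("gxe_", tolower(nm), ".csv"))
      utils::write.csv(stacked, out_path, row.names = FALSE)
      stacked
    }, error = function(e) {
      message("trait ", nm, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- c(failures, nm) else curves[[nm]] <- res
  }
  write_manifest(out_dir, inputs,
                 params = list(max_m = max_m, rg_grid = rg_grid),
                 failures = failures)
  if (length(failures)) {
    stop("failed traits: ", paste(failures, collapse = ", "))
  }
  invisible(curves)
}

#' Run the health-inequality (Gini) analysis
#'
#' Computes the relative Gini curve of individual disease risk for each
#' disease as the fraction of edited genomes varies, writing one CSV per
#' disease (columns \code{fraction}, \code{gini}, \code{relative_gini}) and
#' a JSON summary of the argmax and crossing fractions.
#'
#' @param diseases Named numeric vector of unedited prevalences \code{K}.
#' @param K_prime Named numeric vector of edited prevalences, same names;
#'   defaults to the built-in ten-locus values
#'   ([ten_locus_edited_prevalence()]) for matching names.
#' @param out_dir Output directory.
#' @param fractions Grid of edited fractions (default 0..1 by 0.01).
#' @param n Population size (default 1e6; reduce for quick runs).
#' @param seed Integer seed (default 1).
#' @return Invisibly, a named list of \code{gini_curve} data frames.
#' @export
run_figure3 <- function(diseases = c(AD = 0.05, SCZ = 0.01, T2D = 0.10,
                                     CAD = 0.06, MDD = 0.15),
                        K_prime = ten_locus_edited_prevalence()[names(diseases)],
                        out_dir, fractions = seq(0, 1, by = 0.01),
                        n = 1e6L, seed = 1L) {
  stopifnot(length(diseases) >= 1, all(names(diseases) %in% names(K_prime)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  curves <- list()
  summary <- list()
  for (i in seq_along(diseases)) {
    nm <- names(diseases)[i]
    curve <- gini_curve(K = diseases[[nm]], K_prime = K_prime[[nm]],
                        fractions = fractions, n = n, seed = seed + i)
    utils::write.csv(curve, file.path(out_dir,
                                      paste0("gini_", tolower(nm), ".csv")),
                     row.names = FALSE)
    summary[[nm]] <- list(K = diseases[[nm]], K_prime = K_prime[[nm]],
                          argmax_fraction = attr(curve, "argmax_fraction"),
                          crossing_fraction = attr(curve, "crossing_fraction"))
    curves[[nm]] <- curve
  }
  jsonlite::write_json(summary, file.path(out_dir, "gini_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, inputs = NULL,
                 params = list(diseases = as.list(diseases),
                               K_prime = as.list(K_prime[names(diseases)]),
                               n = n, seed = seed,
                               fractions = range(fractions)))
  invisible(curves)
}

write_manifest <- function(out_dir, inputs, params, failures = character(0)) {
  input_hashes <- if (!is.null(inputs)) {
    paths <- vapply(inputs, function(x) x$path, character(1))
    as.list(stats::setNames(unname(tools::md5sum(paths)), names(inputs)))
  } else NULL
  manifest <- list(package = "polyedit",
                   version = as.character(utils::packageVersion("polyedit")),
                   inputs_md5 = input_hashes,
                   params = params,
                   failures = as.list(failures))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
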