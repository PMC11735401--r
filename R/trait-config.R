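#' Trait configuration
#'
#' Describes a trait analysed under the editing model: either a binary
#' disease, characterised by its lifetime prevalence \code{K} on which the
#' liability threshold depends, or a quantitative trait, characterised by its
#' phenotypic standard deviation in physical units.
#'
#' @param name Trait name (e.g. \code{"AD"}, \code{"LDL"}).
#' @param kind Either \code{"binary"} or \code{"quantitative"}.
#' @param prevalence_K Lifetime prevalence in (0, 1); required for (and only
#'   allowed with) binary traits.
#' @param phenotypic_sd Positive phenotypic standard deviation; required for
#'   (and only allowed with) quantitative traits. May be \code{NA} if it is to
#'   be estimated later from summary statistics (see
#'   [estimate_phenotypic_sd()]).
#' @param units Units string for \code{phenotypic_sd} (e.g. \code{"mmol/l"}).
#'
#' @return An object of class \code{trait_config}.
#' @examples
#' trait_config("AD", "binary", prevalence_K = 0.05)
#' trait_config("LDL", "quantitative", phenotypic_sd = 0.4, units = "mmol/l")
#' @export
trait_config <- function(name, kind = c("binary", "quantitative"),
                         prevalence_K = NULL, phenotypic_sd = NULL,
                         units = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "binary") {
    if (is.null(prevalence_K) || !is.finite(prevalence_K) ||
        prevalence_K <= 0 || prevalence_K >= 1) {
      stop("binary trait '", name, "' requires prevalence_K in (0, 1)")
    }
    if (!is.null(phenotypic_sd)) {
      stop("phenotypic_sd must not be set for a binary trait")
    }
  } else {
    if (!is.null(prevalence_K)) {
      stop("prevalence_K must not be set for a quantitative trait")
    }
    if (is.null(phenotypic_sd)) phenotypic_sd <- NA_real_
    if (!is.na(phenotypic_sd) && phenotypic_sd <= 0) {
      stop("phenotypic_sd must be positive")
    }
  }
  structure(
    list(name = name, kind = kind,
         prevalence_K = if (kind == "binary") prevalence_K else NULL,
         phenotypic_sd = if (kind == "quantitative") phenotypic_sd else NULL,
         units = units),
    class = "trait_config"
  )
}

#' @export
print.trait_config <- function(x, ...) {
  if (x$kind == "binary") {
    cat(sprintf("<trait_config> %s (binary), lifetime prevalence K = %g\n",
                x$name, x$prevalence_K))
  } else {
    cat(sprintf("<trait_config> %s (quantitative), phenotypic sd = %s %s\n",
                x$name, format(x$phenotypic_sd), x$units))
  }
  invisible(x)
}

#' Built-in trait presets
#'
#' The ten traits modelled by the package: five common diseases with their
#' assumed lifetime prevalences (AD 5\%, SCZ 1\%, T2D 10\%, CAD 6\%, MDD
#' 15\%) and five quantitative biomarkers (FG, LDL, TG, SBP, DBP) with
#' representative phenotypic standard deviations in physical units.
#'
#' @param name Optional single trait name; if omitted, the full named list is
#'   returned.
#' @return A \code{trait_config}, or a named list of them.
#' @examples
#' trait_presets("AD")
#' names(trait_presets())
#' @export
trait_presets <- function(name = NULL) {
  presets <- list(
    AD  = trait_config("AD",  "binary", prevalence_K = 0.05),
    SCZ = trait_config("SCZ", "binary", prevalence_K = 0.01),
    T2D = trait_config("T2D", "binary", prevalence_K = 0.10),
    CAD = trait_config("CAD", "binary", prevalence_K = 0.06),
    MDD = trait_config("MDD", "binary", prevalence_K = 0.15),
    FG  = trait_config("FG",  "quantitative", phenotypic_sd = 0.8,
                       units = "mmol/l"),
    LDL = trait_config("LDL", "quantitative", phenotypic_sd = 0.4,
                       units = "mmol/l"),
    TG  = trait_config("TG",  "quantitative", phenotypic_sd = 1.0,
                       units = "mmol/l"),
    SBP = trait_config("SBP", "quantitative", phenotypic_sd = 19,
                       units = "mmHg"),
    DBP = trait_config("DBP", "quantitative", phenotypic_sd = 10,
                       units = "mmHg")
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown trait '", name, "'; valid names: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]]
}

#' Ten-locus edited prevalences for the five modelled diseases
#'
#' Lifetime prevalence among genomes edited at the ten top-ranked
#' genome-wide-significant loci, as used for the inequality mixture analysis
#' (K'). CAD is derived from its fold change in prevalence (6\% / 32.2),
#' which carries more significant figures than the rounded prevalence.
#'
#' @return Named numeric vector of proportions.
#' @examples
#' ten_locus_edited_prevalence()
#' @export
ten_locus_edited_prevalence <- function() {
  c(AD = 0.006, SCZ = 0.001, T2D = 0.002, CAD = 0.06 / 32.2, MDD = 0.09)
}

#' Read trait configurations from a YAML file
#'
#' The file maps trait name to a block with \code{kind} and either
#' \code{prevalence_K} (binary) or \code{phenotypic_sd}/\code{units}
#' (quantitative), and may carry an optional \code{column_mapping} block used
#' by [read_locus_table()].
#'
#' @param path Path to a YAML file.
#' @return A list with elements \code{traits} (named list of
#'   \code{trait_config}) and \code{column_mapping} (named character vector,
#'   possibly empty).
#' @export
read_trait_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  col_map <- raw$column_mapping
  raw$column_mapping <- NULL
  traits <- lapply(names(raw), function(nm) {
    blk <- raw[[nm]]
    trait_config(nm, kind = blk$kind,
                 prevalence_K = blk$prevalence_K,
                 phenotypic_sd = blk$phenotypic_sd,
                 units = blk$units %||% NA_character_)
  })
  names(traits) <- names(raw)
  list(traits = traits,
       column_mapping = unlist(col_map) %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
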