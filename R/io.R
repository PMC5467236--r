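## Particle-table CSV and config-JSON interchange.

#' Write an ensemble to CSV with a JSON config sidecar
#'
#' The particle table has one row per subunit with columns
#' \code{particle_id}, \code{subunit_index}, \code{n_subunits},
#' \code{radius_A}, \code{separation_A}, \code{paired}, \code{compact}
#' (plus \code{x_A}, \code{y_A} in angular mode). The sidecar stores the
#' full generator configuration, including the seed, so a written ensemble
#' is exactly regenerable.
#'
#' @param ensemble a \linkS4class{HoloEnsemble}.
#' @param csvPath output CSV path.
#' @param configPath output JSON path; default replaces the CSV extension
#'   with \code{.config.json}.
#' @return \code{csvPath}, invisibly.
#' @export
writeEnsemble <- function(ensemble, csvPath,
                          configPath = sub("\\.csv$", ".config.json", csvPath)) {
  stopifnot(is(ensemble, "HoloEnsemble"))
  utils::write.csv(ensemble@subunits, csvPath, row.names = FALSE)
  cfg <- ensemble@config
  lst <- sapply(slotNames(cfg), function(s) {
    v <- slot(cfg, s)
    if (!is.null(names(v))) as.list(v) else v  # keep names in the JSON
  }, simplify = FALSE)
  jsonlite::write_json(lst, configPath, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}

#' Read a particle table CSV
#'
#' @param csvPath path to a particle table written by [writeEnsemble()] (or
#'   assembled externally in the same long format).
#' @return validated measurement \code{data.frame}.
#' @export
readParticleTable <- function(csvPath) {
  tab <- utils::read.csv(csvPath)
  need <- c("particle_id", "subunit_index", "n_subunits",
            "radius_A", "separation_A")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("particle table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(tab$radius_A <= 0, na.rm = TRUE) ||
      any(tab$separation_A <= 0, na.rm = TRUE))
    stop("radii and separations must be positive", call. = FALSE)
  tab
}

#' Read an ensemble back from CSV + JSON sidecar
#'
#' @param csvPath particle-table CSV.
#' @param configPath JSON sidecar with the generator configuration.
#' @return a \linkS4class{HoloEnsemble}.
#' @export
readEnsemble <- function(csvPath,
                         configPath = sub("\\.csv$", ".config.json", csvPath)) {
  tab <- readParticleTable(csvPath)
  lst <- jsonlite::read_json(configPath, simplifyVector = TRUE)
  cfg <- ensembleConfig(
    nParticles = lst$nParticles, seed = lst$seed, mode = lst$mode,
    pTetradecamer = lst$pTetradecamer, hubRadius = lst$hubRadius,
    kinaseRadius = lst$kinaseRadius, pCompact = lst$pCompact,
    radiusExtended = unlist(lst$radiusExtended),
    radiusCompact = unlist(lst$radiusCompact),
    pairCountProbs = unlist(lst$pairCountProbs),
    sepPaired = unlist(lst$sepPaired),
    sepUnpaired = unlist(lst$sepUnpaired),
    angularPairedGap = unlist(lst$angularPairedGap),
    angularUnpairedSd = lst$angularUnpairedSd)
  new("HoloEnsemble", subunits = tab, config = cfg)
}
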