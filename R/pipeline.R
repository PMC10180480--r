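## Pipeline commands tying the stages into reproducible, seeded runs with
## structured reports.

#' Read a run configuration file
#'
#' @param path YAML (.yml/.yaml) or JSON (.json) configuration file with
#'   per-command parameter blocks.
#' @return a named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: ", ext)
  }
}

.design_from_config <- function(config) {
  dc <- config$design
  if (is.null(dc)) return(FUnitDesign())
  do.call(FUnitDesign, dc[names(dc) %in% names(formals(FUnitDesign))])
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

.report <- function(command, sections, config, seed) {
  new("RunReport", command = command, sections = sections,
      provenance = list(configHash = .config_hash(config), seed = seed,
                        package = "sheetkit",
                        version = as.character(utils::packageVersion("sheetkit"))))
}

.cmd_design_report <- function(config, seed) {
  design <- .design_from_config(config)
  if (!length(design@sequences)) design <- makeDesignSequences(design, seed)
  theta <- config$junctionAngleDeg %||% 80
  lattice <- poreLatticeGeometry(design, theta)
  chol <- cholesterolSpacings(design)
  tms <- domainMeltingTemperatures(design)
  list(
    design_checks = validateDesign(design),
    melting_temperatures_C = list(core = tms@tmCore, arm = tms@tmArm,
                                  se1 = tms@tmSe1, se2 = tms@tmSe2),
    lattice = list(side_long_bp = lattice@sideLongBp,
                   side_short_bp = lattice@sideShortBp,
                   side_long_nm = lattice@sideLongNm,
                   side_short_nm = lattice@sideShortNm,
                   junction_angle_deg = lattice@junctionAngleDeg,
                   diag_long_nm = lattice@diagLongNm,
                   diag_short_nm = lattice@diagShortNm,
                   porosity_percent = 100 * lattice@porosityFraction),
    cholesterol_spacings_nm = list(min = chol$minNm, max = chol$maxNm))
}

.cmd_simulate <- function(config, seed, outDir) {
  design <- .design_from_config(config)
  rc <- config$relaxation %||% list()
  rc$seed <- rc$seed %||% seed
  relax <- do.call(RelaxationParams,
                   rc[names(rc) %in% names(formals(RelaxationParams))])
  gen <- generateRelaxationTrajectory(design, relax, dir = outDir)
  list(files = list(topology = gen$topologyPath,
                    trajectory = gen$trajectoryPath,
                    ground_truth = gen$groundTruthPath),
       n_frames = relax@nFrames,
       equilibrium_tilt_deg = relax@equilibriumTiltDeg)
}

.cmd_analyze_junction <- function(config, seed, outDir) {
  design <- .design_from_config(config)
  if (is.null(config$trajectory)) {
    rc <- config$relaxation %||% list()
    rc$seed <- rc$seed %||% seed
    relax <- do.call(RelaxationParams,
                     rc[names(rc) %in% names(formals(RelaxationParams))])
    gen <- generateRelaxationTrajectory(design, relax, dir = outDir)
    traj <- gen$trajectory
    junctions <- gen$junctions
    pairing <- gen$pairing
  } else {
    top <- readTopology(config$topology)
    traj <- readTrajectory(config$trajectory, top)
    if (!length(design@sequences)) design <- makeDesignSequences(design, seed)
    pairing <- deriveBasePairs(top, mode = "design", design = design)
    lay <- .funit_layout(design)
    junctions <- list(
      JunctionSpec(1, lay$junction1, c(e1 = FALSE, e2 = TRUE, e3 = NA)),
      JunctionSpec(2, lay$junction2, c(e4 = FALSE, e5 = TRUE, e6 = NA)))
  }
  frac <- config$lastFraction %||% 0.5
  out <- lapply(junctions, function(j) {
    s <- equilibriumStats(planaritySeries(traj, pairing, j), frac)
    list(metric = s@metric, units = s@units,
         equilibrium_mean = s@equilibriumMean,
         equilibrium_sd = s@equilibriumSd,
         window_tauB = s@window)
  })
  names(out) <- vapply(out, `[[`, character(1), "metric")
  out
}

.cmd_analyze_pore <- function(config, seed) {
  design <- .design_from_config(config)
  theta <- config$junctionAngleDeg %||% 80
  dc <- config$distortion %||% list()
  dc$seed <- dc$seed %||% seed
  dist <- do.call(DistortionParams,
                  dc[names(dc) %in% names(formals(DistortionParams))])
  gen <- generatePoreSnapshot(design, theta, dist)
  quad <- poreQuadrilateral(gen$snapshot, gen$pairing, gen$pore)
  ang <- poreInternalAngles(gen$snapshot, gen$pairing, gen$pore)
  nrm <- cornerPlanePlanarity(quad$corners)
  list(diagonals_nm = list(XZ = quad$diagXZNm, YW = quad$diagYWNm),
       internal_angles_deg = as.list(ang),
       corner_normal_angles_deg = as.list(nrm))
}

.cmd_afm_profile <- function(config, seed) {
  if (!is.null(config$profile)) {
    prof <- readHeightProfile(config$profile)
  } else {
    pc <- config$heightProfile %||% list()
    pc$seed <- pc$seed %||% seed
    prof <- do.call(generateHeightProfile,
                    pc[names(pc) %in% names(formals(generateHeightProfile))])$profile
  }
  res <- analyzeHeightProfile(prof, config$layerHeightNm %||% 2.0)
  list(n_peaks = length(res$peakPositionsNm),
       mean_spacing_nm = res$meanSpacingNm,
       sd_spacing_nm = res$sdSpacingNm,
       layer_counts = res$layerCounts)
}

.cmd_mechanics <- function(config, seed) {
  p <- config$mechanics %||% list()
  params <- ExtrapolationParams(
    thicknessNm = p$thicknessNm %||% 2,
    poissonRatio = p$poissonRatio %||% 0.5,
    porosityFraction = p$porosityFraction %||% 0.40)
  sections <- list()
  Gs <- p$interfacialModulus
  if (!is.null(config$sweep)) {
    sweep <- readTimeSweep(config$sweep)
    seg <- segmentTimeSweep(sweep,
                            temperatureTrigger = p$temperatureTrigger,
                            trailingFraction = p$trailingFraction %||% 0.25)
    sections$phases <- seg
    last <- seg[nrow(seg), ]
    if (is.null(Gs)) Gs <- last$meanGp
    sections$elastic_gap_orders <- elasticGapOrders(last$meanGp, last$meanGpp)
  }
  if (is.null(Gs)) stop("mechanics needs an interfacialModulus or a sweep file")
  res <- extrapolateModulus(Gs, params)
  sections$extrapolation <- list(
    interfacial_modulus_N_per_m = Gs,
    thickness_nm = params@thicknessNm,
    poisson_ratio = params@poissonRatio,
    porosity_fraction = params@porosityFraction,
    bulk_young_modulus_MPa = res@bulkYoungModulusPa / 1e6,
    porosity_corrected_modulus_MPa = res@porosityCorrectedModulusPa / 1e6)
  sections
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a pipeline command
#'
#' Commands: `design-report` (design validation, melting temperatures and
#' idealized lattice predictions), `simulate` (synthetic relaxation
#' trajectory), `analyze-junction` (junction planarity equilibria from a
#' trajectory), `analyze-pore` (pore diagonals, internal angles and
#' corner-plane planarity), `afm-profile` (height-profile pore spacing and
#' layer counts) and `mechanics` (phase plateaus and bulk-modulus
#' extrapolation).  Outputs are deterministic given (config, seed).
#'
#' @param name command name.
#' @param config named list (see [readRunConfig()]).
#' @param seed integer seed for every stochastic stage (default 1,
#'   overridden by `config$seed`).
#' @param outDir directory for generated files (default `tempdir()`).
#' @return a [RunReport-class].
#' @examples
#' rep <- runCommand("mechanics",
#'                   list(mechanics = list(interfacialModulus = 0.3)))
#' rep@sections$extrapolation$bulk_young_modulus_MPa  # 450
#' @export
runCommand <- function(name = c("design-report", "simulate",
                                "analyze-junction", "analyze-pore",
                                "afm-profile", "mechanics"),
                       config = list(), seed = 1, outDir = tempdir()) {
  name <- match.arg(name)
  seed <- config$seed %||% seed
  sections <- switch(name,
    "design-report" = .cmd_design_report(config, seed),
    "simulate" = .cmd_simulate(config, seed, outDir),
    "analyze-junction" = .cmd_analyze_junction(config, seed, outDir),
    "analyze-pore" = .cmd_analyze_pore(config, seed),
    "afm-profile" = .cmd_afm_profile(config, seed),
    "mechanics" = .cmd_mechanics(config, seed))
  .report(name, sections, config, seed)
}

.render_text <- function(x, indent = 0) {
  pad <- strrep("  ", indent)
  out <- character(0)
  if (is.data.frame(x)) {
    return(paste0(pad, utils::capture.output(print(x, row.names = FALSE))))
  }
  if (is.list(x)) {
    for (nm in names(x)) {
      v <- x[[nm]]
      if (is.list(v) || is.data.frame(v)) {
        out <- c(out, paste0(pad, nm, ":"), .render_text(v, indent + 1))
      } else {
        out <- c(out, paste0(pad, nm, ": ", paste(format(v), collapse = " ")))
      }
    }
    return(out)
  }
  paste0(pad, paste(format(x), collapse = " "))
}

#' Write a run report to disk
#'
#' @param report a [RunReport-class].
#' @param path output file path.
#' @param format `"json"` (machine readable) or `"text"`.
#' @return invisibly, `path`.
#' @export
writeReport <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  payload <- list(command = report@command, sections = report@sections,
                  provenance = report@provenance)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    writeLines(c(sprintf("sheetkit report: %s", report@command),
                 .render_text(payload$sections),
                 "provenance:", .render_text(payload$provenance, 1)), path)
  }
  invisible(path)
}
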