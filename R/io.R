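# Plain-text interchange formats: 3-column TSV work traces, profile
# TSV, YAML toy-system/restraint configs, JSON cycle reports.

.WORK_COLS <- c("time_ps", "lambda", "work_kcal_mol")

#' Write a work trace as TSV
#'
#' Three tab-separated columns (`time_ps`, `lambda`, `work_kcal_mol`)
#' with a header line; full double precision so a round trip is
#' lossless to 1e-9 relative.
#'
#' @param trace A [work_trace()] (or data frame with the same columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_work_tsv <- function(trace, path) {
  stopifnot(all(.WORK_COLS %in% names(trace)))
  df <- as.data.frame(trace)[, .WORK_COLS]
  out <- c(paste(.WORK_COLS, collapse = "\t"),
           if (nrow(df)) sprintf("%.17g\t%.17g\t%.17g",
                                 df$time_ps, df$lambda, df$work_kcal_mol))
  writeLines(out, path)
  invisible(path)
}

#' Read a work trace from TSV
#'
#' @param path Path to a file written by [write_work_tsv()].
#' @return A [work_trace()].
#' @export
read_work_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "numeric")
  if (!identical(names(df), .WORK_COLS))
    stop("format error: expected columns ", paste(.WORK_COLS, collapse = ", "))
  if (nrow(df) && any(!is.finite(as.matrix(df))))
    stop("format error: non-finite values in work trace")
  work_trace(df$time_ps, df$lambda, df$work_kcal_mol)
}

#' Write a free-energy profile as TSV
#' @param profile An `fe_profile` from [build_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  out <- c("lambda\tdF\terr",
           sprintf("%.17g\t%.17g\t%.17g", profile$lambda, profile$dF,
                   profile$err))
  writeLines(out, path)
  invisible(path)
}

#' Read a free-energy profile from TSV
#' @param path Path to a file written by [write_profile_tsv()].
#' @return An `fe_profile` data frame.
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "numeric")
  if (!identical(names(df), c("lambda", "dF", "err")))
    stop("format error: expected columns lambda, dF, err")
  structure(df, class = c("fe_profile", "data.frame"))
}

#' Serialize a toy system and restraint set to a YAML config
#'
#' @param system A [toy_system()].
#' @param restraints A [restraint_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toy_config <- function(system, restraints, path) {
  cfg <- list(
    units = list(energy = "kcal/mol", length = "Angstrom", time = "ps",
                 mass = "amu"),
    system = list(
      positions = apply(system$positions, 1, as.numeric, simplify = FALSE),
      masses = as.numeric(system$masses),
      monomer = as.character(system$monomer),
      epsilon = system$epsilon, sigma = system$sigma,
      interface = system$interface,
      bonds = if (is.null(system$bonds)) NULL else
        lapply(seq_len(nrow(system$bonds)), function(i)
          as.list(system$bonds[i, ])),
      reference = apply(system$reference, 1, as.numeric, simplify = FALSE)
    ),
    restraints = list(
      cv = list(k = restraints$cv_k, center = restraints$cv_center),
      rmsd_k = as.numeric(restraints$rmsd_k),
      planar_k = as.numeric(restraints$planar_k),
      planar_targets = apply(restraints$planar_targets, 1, as.numeric,
                             simplify = FALSE),
      points = if (is.null(restraints$points)) NULL else
        lapply(seq_len(nrow(restraints$points)), function(i)
          as.list(restraints$points[i, ])),
      flat_bottom = restraints$flat_bottom
    )
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a toy system and restraint set from a YAML config
#' @param path Path written by [write_toy_config()].
#' @return List with `system` and `restraints`.
#' @export
read_toy_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  s <- cfg$system
  pos <- do.call(rbind, s$positions)
  sys <- toy_system(pos, s$masses, s$monomer, epsilon = s$epsilon,
                    sigma = s$sigma,
                    bonds = if (is.null(s$bonds)) NULL else
                      do.call(rbind, lapply(s$bonds, as.data.frame)),
                    reference = do.call(rbind, s$reference),
                    interface = s$interface)
  r <- cfg$restraints
  rs <- restraint_set(
    cv_k = r$cv$k, cv_center = r$cv$center,
    rmsd_k = r$rmsd_k, planar_k = r$planar_k,
    planar_targets = do.call(rbind, r$planar_targets),
    points = if (is.null(r$points)) NULL else
      do.call(rbind, lapply(r$points, as.data.frame)),
    flat_bottom = r$flat_bottom
  )
  list(system = sys, restraints = rs)
}

#' Write a one-page cycle report (JSON and text)
#'
#' @param result A `cycle_result` from [assemble_cycle()].
#' @param path Output path for the JSON report; a `.txt` twin is
#'   written alongside it.
#' @return `path`, invisibly.
#' @export
write_cycle_report <- function(result, path) {
  c <- result$components
  obj <- list(
    dF_A = c$dF_A, s_A = c$s_A, dF_B = c$dF_B, s_B = c$s_B,
    dF_C = c$dF_C, s_C = c$s_C, dF_V = c$dF_V, dF_R = c$dF_R,
    temperature_K = c$temperature,
    binding_free_energy = result$dF, sigma = result$sigma,
    note = "steering along a fixed axis; no Jacobian correction needed"
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  con <- file(txt, "w"); on.exit(close(con))
  sink(con); print(result); sink()
  invisible(path)
}

#' Write a reproducibility manifest for a run
#'
#' Records the configuration hash, master seed and package version so
#' an output directory can be regenerated bit-identically.
#'
#' @param config_path Path of the config the run used (hashed with
#'   md5).
#' @param seed Master seed of the run.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config_path, seed, path) {
  obj <- list(
    config = config_path,
    config_md5 = unname(tools::md5sum(config_path)),
    seed = seed,
    package = "smdcycle",
    version = as.character(utils::packageVersion("smdcycle")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}
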