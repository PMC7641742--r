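## PDB conformer/ensemble I/O and run configuration.

.pdb_atom_field <- function(name) {
  # wwPDB alignment: names of up to 3 characters start in column 14
  if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
}

.pdb_lines_one <- function(conf, serial0 = 0L) {
  n <- nrow(conf)
  lines <- character(n)
  for (i in seq_len(n)) {
    lines[i] <- sprintf(
      "ATOM  %5d %s %-3s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial0 + i, .pdb_atom_field(conf$atom[i]), conf$resname[i], " A",
      conf$resno[i], conf$x[i], conf$y[i], conf$z[i], 1, 0, conf$element[i])
  }
  c(lines, sprintf("TER   %5d      %-3s%s%4d", serial0 + n + 1L,
                   conf$resname[n], " A", conf$resno[n]))
}

#' Write a conformer or ensemble as PDB
#'
#' Conformers are written as a single chain of ATOM records (chain A,
#' 1-based residue numbering, DA/DC/DG/DT residue names, element column,
#' terminating TER); ensembles as multi-MODEL files containing the flagged
#' conformers (or all conformers when none are flagged).
#'
#' @param x A [conformer()] or `qdh_ensemble`.
#' @param path Output path.
#' @param flagged_only For ensembles, write only the flagged subset.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, flagged_only = TRUE) {
  if (inherits(x, "conformer")) {
    writeLines(c(.pdb_lines_one(x), "END"), path)
    return(invisible(path))
  }
  confs <- x$conformers
  if (flagged_only && length(x$flagged)) confs <- confs[x$flagged]
  out <- character()
  for (m in seq_along(confs)) {
    out <- c(out, sprintf("MODEL     %4d", m),
             .pdb_lines_one(confs[[m]]), "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read a PDB file into a conformer or ensemble
#'
#' Parses ATOM/HETATM records (fixed columns); multi-MODEL files yield an
#' ensemble of equal-size conformers, single-model files a conformer.
#' A malformed or truncated record raises an error naming the line.
#'
#' @param path PDB file path.
#' @return A [conformer()], or a `qdh_ensemble` for multi-MODEL files.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  models <- list()
  cur <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    rec <- substr(line, 1, 6)
    if (rec == "MODEL ") {
      cur <- list()
    } else if (rec == "ENDMDL") {
      models[[length(models) + 1]] <- cur
      cur <- list()
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      if (nchar(line) < 54)
        stop(sprintf("malformed ATOM record at line %d: too short", ln))
      xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                           substr(line, 39, 46),
                                           substr(line, 47, 54))))
      resno <- suppressWarnings(as.integer(substr(line, 23, 26)))
      if (anyNA(xyz) || is.na(resno))
        stop(sprintf("malformed ATOM record at line %d: bad numeric field",
                     ln))
      el <- trimws(substr(line, 77, 78))
      nm <- trimws(substr(line, 13, 16))
      if (el == "") el <- substr(nm, 1, 1)
      cur[[length(cur) + 1]] <- data.frame(
        resno = resno, resname = trimws(substr(line, 18, 20)), atom = nm,
        element = el, x = xyz[1], y = xyz[2], z = xyz[3],
        stringsAsFactors = FALSE)
    }
  }
  if (length(cur)) models[[length(models) + 1]] <- cur
  models <- models[vapply(models, length, 0L) > 0]
  if (!length(models)) stop("no ATOM records found in ", path)
  confs <- lapply(models, function(m) conformer(do.call(rbind, m)))
  if (length(confs) == 1) return(confs[[1]])
  structure(list(conformers = confs,
                 energies = rep(NA_real_, length(confs)),
                 flagged = seq_along(confs), failed = integer(),
                 topology = NA_character_),
            class = "qdh_ensemble")
}

#' Run configuration for the structure-calculation pipeline
#'
#' A YAML document holding the pipeline inputs: `topology` (path),
#' optional `peaks` (path), `n_structures`, `n_select`, `seed`,
#' `scale_factor` and any [anneal_schedule()] field overrides under
#' `schedule`.
#'
#' @param path YAML config path.
#' @return Named list with a populated `schedule` element.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(n_structures = 100L, n_select = 10L, seed = 1L,
                   scale_factor = 1)
  cfg <- utils::modifyList(defaults, cfg)
  sched_args <- cfg$schedule
  if (is.null(sched_args)) sched_args <- list()
  sched_args$scale_factor <- cfg$scale_factor
  cfg$schedule <- do.call(anneal_schedule, sched_args)
  cfg
}
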