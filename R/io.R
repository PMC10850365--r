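#' Read / write a property series as CSV
#'
#' Two-column CSV (`time_ps`, `value`) with a one-line header; extra value
#' columns can be selected with `column`. The time column must be strictly
#' increasing and uniform — violations are rejected with the offending row
#' named, never silently repaired.
#'
#' @param path File path.
#' @param column Value column to read (name or index; default 2).
#' @param label Series label (default: the column name).
#' @return [read_series_csv()]: a [property_series()].
#' @export
read_series_csv <- function(path, column = 2, label = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("empty series: '", path,
                          "' has a header but no rows", call. = FALSE)
  if (ncol(df) < 2) stop("need at least 2 columns (time, value)",
                         call. = FALSE)
  tcol <- df[[1]]
  vcol <- df[[column]]
  if (!is.numeric(tcol) || !is.numeric(vcol)) {
    stop("non-numeric time or value column", call. = FALSE)
  }
  steps <- diff(tcol)
  if (any(steps <= 0)) {
    stop("time column not strictly increasing at row ",
         which(steps <= 0)[1] + 1, call. = FALSE)
  }
  if (is.null(label)) {
    label <- if (is.character(column)) column else names(df)[column]
  }
  property_series(vcol, times = tcol, label = label)
}

#' @rdname read_series_csv
#' @param series A [property_series()].
#' @return [write_series_csv()]: `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "property_series"))
  df <- data.frame(time_ps = series$times, value = series$values)
  names(df)[2] <- make.names(series$label)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a decorrelation curve as CSV
#'
#' Columns `t_ps`, `tau_c_ps`, `crossing_found`.
#'
#' @param dc A [decorrelation_curve()].
#' @param path File path.
#' @export
write_dc_csv <- function(dc, path) {
  stopifnot(inherits(dc, "decorrelation_curve"))
  utils::write.csv(as.data.frame(dc), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dc_csv
#' @return [read_dc_csv()]: a `decorrelation_curve`.
#' @export
read_dc_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t_ps", "tau_c_ps", "crossing_found") %in% names(df)))
  class(df) <- c("decorrelation_curve", "data.frame")
  df
}

#' Read / write conformational ensembles as multi-model PDB
#'
#' Multi-model PDB (MODEL/ENDMDL records) carrying one conformation per
#' model; reading filters to one atom type (default C-alpha, atom name
#' "CA"), giving one node per residue in residue order. Parsing and
#' fixed-width writing are delegated to bio3d, the standard structural
#' bioinformatics reader. Models with mismatched atom counts are rejected
#' naming the model. Frame times are synthesised from `dt_ps` (PDB files
#' carry no time axis; the stride must be declared, never guessed).
#'
#' @param path File path.
#' @param atom_filter Atom name to keep (default `"CA"`; `NULL` keeps
#'   all).
#' @param dt_ps Declared frame stride in ps (default 1).
#' @return [read_pdb_models()]: a [coordinate_ensemble()].
#' @export
read_pdb_models <- function(path, atom_filter = "CA", dt_ps = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- if (is.null(atom_filter)) {
    seq_len(nrow(pdb$atom))
  } else {
    which(trimws(pdb$atom$elety) == atom_filter)
  }
  if (!length(sel)) stop("no atoms match filter '", atom_filter, "'",
                         call. = FALSE)
  xyz_idx <- as.numeric(vapply(sel, function(i) 3 * (i - 1) + 1:3,
                               numeric(3)))
  xyz <- pdb$xyz[, xyz_idx, drop = FALSE]
  nf <- nrow(xyz)
  na <- length(sel)
  coords <- array(0, c(nf, na, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  coordinate_ensemble(coords,
                      times = dt_ps * (seq_len(nf) - 1),
                      residue_index = pdb$atom$resno[sel],
                      atom_name = trimws(pdb$atom$elety[sel]))
}

#' @rdname read_pdb_models
#' @param ensemble A [coordinate_ensemble()].
#' @param resid Residue name written for every atom (default `"ALA"`).
#' @export
write_pdb_models <- function(ensemble, path, resid = "ALA") {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  nf <- dim(ensemble$coords)[1]
  na <- dim(ensemble$coords)[2]
  xyz <- t(vapply(seq_len(nf), function(f) as.numeric(t(ensemble$coords[f, , ])),
                  numeric(3 * na)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = ensemble$residue_index,
                   resid = rep(resid, na),
                   elety = ensemble$atom_name,
                   chain = rep("A", na))
  invisible(path)
}

#' Load a trajectory through the format adapter
#'
#' Routes a trajectory file to the matching reader by extension (or an
#' explicit hint) and returns a uniform [coordinate_ensemble()]. Currently
#' multi-model PDB is supported natively; binary MD formats would plug in
#' here behind the same seam.
#'
#' @param path File path.
#' @param format Format hint (default: file extension). Supported:
#'   `"pdb"`.
#' @param ... Passed to the underlying reader.
#' @return A [coordinate_ensemble()].
#' @export
trajectory_adapter <- function(path, format = NULL, ...) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  supported <- c("pdb")
  if (!format %in% supported) {
    stop("unsupported trajectory format '", format, "'; supported: ",
         paste(supported, collapse = ", "), call. = FALSE)
  }
  switch(format, pdb = read_pdb_models(path, ...))
}

#' Serialize a mode set
#'
#' Writes the mode vectors as a CSV matrix and the metadata (eigenvalues,
#' provenance, reference coordinates) as JSON next to it.
#'
#' @param modes A [mode_set()].
#' @param path Base path; `<path>.csv` and `<path>.json` are written.
#' @export
write_mode_set <- function(modes, path) {
  stopifnot(inherits(modes, "mode_set"))
  utils::write.csv(as.data.frame(modes$vectors), paste0(path, ".csv"),
                   row.names = FALSE)
  meta <- list(eigenvalues = modes$eigenvalues,
               provenance = modes$provenance,
               reference = modes$reference)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mode_set
#' @return [read_mode_set()]: a [mode_set()].
#' @export
read_mode_set <- function(path) {
  vec <- as.matrix(utils::read.csv(paste0(path, ".csv")))
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  ref <- if (!is.null(meta$reference)) as.matrix(meta$reference) else NULL
  mode_set(unname(vec), meta$eigenvalues, provenance = meta$provenance,
           reference = ref)
}

#' Write a free-energy surface
#'
#' CSV grid of F values (1D: two columns; 2D: matrix with bin-centre
#' headers) plus a JSON sidecar with bin edges, thermal energy and the
#' empty-bin mask.
#'
#' @param surface A [pmf()] result.
#' @param path Base path; `<path>.csv` and `<path>.json` are written.
#' @export
write_fes <- function(surface, path) {
  stopifnot(inherits(surface, "free_energy_surface"))
  Fv <- surface$F
  if (is.matrix(Fv)) {
    utils::write.csv(Fv, paste0(path, ".csv"), row.names = FALSE)
  } else {
    ex <- surface$edges[[1]]
    utils::write.csv(data.frame(bin_center = (ex[-1] + ex[-length(ex)]) / 2,
                                F_kcal_mol = Fv),
                     paste0(path, ".csv"), row.names = FALSE)
  }
  meta <- list(edges = surface$edges, kbt = surface$kbt,
               bin_width = surface$bin_width,
               empty = which(is.na(Fv)))
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA)
  invisible(path)
}
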