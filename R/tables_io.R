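# Fixed-header CSV writers/readers for the tabular outputs, so results
# round-trip between pipeline stages and external tools.

foci_columns <- c("focus_id", "channel", "x_um", "y_um", "z_um", "n_voxels",
                  "volume_um3", "integrated_density", "average_intensity",
                  "peak_intensity", "nucleus_id", "compartment",
                  "d_center_um", "d_edge_um", "rho", "rho_clamped", "zone")

nuclei_columns <- c("nucleus_id", "x_um", "y_um", "z_um", "r_um",
                    "volume_um3", "n_voxels")

#' Write a foci table to CSV
#'
#' Writes the documented fixed header (missing columns are filled with NA so
#' the header is stable across pipeline stages).
#'
#' @param foci a [detect_foci()] table
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_foci_csv <- function(foci, path) {
  for (col in setdiff(foci_columns, names(foci))) foci[[col]] <- NA
  write.csv(foci[, foci_columns, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a foci table written by [write_foci_csv()]
#' @param path CSV file
#' @return data.frame
#' @export
read_foci_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("focus_id", "x_um", "y_um", "z_um"), names(df))
  if (length(missing)) stop("foci CSV lacks column(s): ",
                            paste(missing, collapse = ", "))
  df
}

#' Write a nucleus table to CSV
#' @param nuclei a [segment_nuclei()] result or its `table`
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_nuclei_csv <- function(nuclei, path) {
  tab <- if (inherits(nuclei, "NucleusSet")) nuclei$table else nuclei
  for (col in setdiff(nuclei_columns, names(tab))) tab[[col]] <- NA
  extra <- setdiff(names(tab), nuclei_columns)
  write.csv(tab[, c(nuclei_columns, extra), drop = FALSE], path,
            row.names = FALSE)
  invisible(path)
}

#' Read a nucleus table written by [write_nuclei_csv()]
#' @param path CSV file
#' @return data.frame
#' @export
read_nuclei_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("nucleus_id", "x_um", "y_um", "z_um", "r_um"),
                     names(df))
  if (length(missing)) stop("nuclei CSV lacks column(s): ",
                            paste(missing, collapse = ", "))
  df
}
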