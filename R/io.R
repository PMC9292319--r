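# Readers and writers for the delimited-text table schemas.

#' Read an individual-level trait table
#'
#' Comma-separated, header row, UTF-8, missing values as empty fields.
#' Expected columns: `individual_id`, `species`, `plot`, optionally
#' `habit`, plus the canonical trait columns (see [trait_names()]).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("individual_id", "species", "plot")
  if (!all(need %in% names(df))) {
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Read a two-census tree inventory table
#'
#' Columns: `tree_id`, `species`, `plot`, `status`
#' (survivor/dead/recruit), `dbh_t0`, `height_t0`, `dbh_tfin`, `date_t0`,
#' `date_tfin` (ISO-8601), optionally `wood_density`.
#'
#' @param path file path.
#' @return data frame with `Date` date columns.
#' @export
read_census_table <- function(path) {
  if (!file.exists(path)) stop("census table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  df$date_t0 <- as.Date(df$date_t0)
  df$date_tfin <- as.Date(df$date_tfin)
  df
}

#' Read a species-by-plot wood density table
#'
#' Columns: `species`, `plot`, `wood_density` (g cm^-3).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_wood_density_table <- function(path) {
  if (!file.exists(path)) stop("wood density table not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

.write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Write the three input tables of a synthetic community
#'
#' @param community a [generate_community()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "synthetic_community"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("trait_table.csv", "census_table.csv",
                            "wood_density_table.csv",
                            "true_latent_scores.csv"))
  .write_table(community$trait_table, paths[1])
  .write_table(community$census_table, paths[2])
  .write_table(community$wood_density_table, paths[3])
  .write_table(community$true_latent_scores, paths[4])
  invisible(paths)
}

#' Write a TPD as a delimited matrix with a header block
#'
#' The header (comment lines starting `#`) records the axis ranges and
#' cell counts; the body is the cells-per-axis-1 by cells-per-axis-2 mass
#' matrix.
#'
#' @param tpd a `tpd` object.
#' @param path file path.
#' @export
write_tpd <- function(tpd, path) {
  g <- tpd$grid
  hdr <- c(sprintf("# axis1 %.10g %.10g", g$min[1], g$max[1]),
           sprintf("# axis2 %.10g %.10g", g$min[2], g$max[2]),
           sprintf("# cells %d %d", g$cells[1], g$cells[2]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(matrix(tpd$mass, g$cells[1], g$cells[2]), con,
                     row.names = FALSE, col.names = FALSE, sep = ",")
}

#' Read a TPD written by [write_tpd()]
#'
#' @param path file path.
#' @return a `tpd` object.
#' @export
read_tpd <- function(path) {
  if (!file.exists(path)) stop("TPD file not found: ", path)
  hdr <- readLines(path, n = 3)
  ax1 <- as.numeric(strsplit(hdr[1], " ")[[1]][3:4])
  ax2 <- as.numeric(strsplit(hdr[2], " ")[[1]][3:4])
  cells <- as.integer(strsplit(hdr[3], " ")[[1]][3:4])
  m <- as.matrix(utils::read.table(path, skip = 3, sep = ","))
  w <- c((ax1[2] - ax1[1]) / cells[1], (ax2[2] - ax2[1]) / cells[2])
  g <- structure(list(min = c(ax1[1], ax2[1]), max = c(ax1[2], ax2[2]),
                      cells = cells,
                      x1 = ax1[1] + (seq_len(cells[1]) - 0.5) * w[1],
                      x2 = ax2[1] + (seq_len(cells[2]) - 0.5) * w[2],
                      cell_width = w, cell_area = prod(w),
                      ncell = prod(cells)), class = "tpd_grid")
  structure(list(mass = as.vector(m), grid = g, population = NULL,
                 n_obs = NA_integer_), class = "tpd")
}
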