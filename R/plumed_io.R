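#' PLUMED-dialect whitespace tables (COLVAR / HILLS)
#'
#' Both file kinds are plain whitespace-separated numeric tables with a
#' `#! FIELDS <names...>` header line; HILLS files carry one deposited
#' Gaussian per row (time, centers, sigmas, height, bias factor).
#'
#' @param df data.frame of numeric columns.
#' @param path output path.
#' @param digits significant digits written (default 10).
#' @return `path`, invisibly.
#' @export
write_plumed_table <- function(df, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(df), collapse = " ")), con)
  body <- do.call(paste, c(lapply(df, function(x)
    formatC(x, digits = digits, format = "g")), sep = " "))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_plumed_table
#' @export
read_plumed_table <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^#!\\s*FIELDS", header))
    stop("not a PLUMED-style table (missing '#! FIELDS' header): ", path)
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", header)), "\\s+")[[1]]
  df <- utils::read.table(path, comment.char = "#", header = FALSE,
                          col.names = fields)
  df
}

#' Write a CV series as a COLVAR file
#'
#' @param cv an `hj_cv_series` (or any data.frame with a `time`
#'   column); the `frame` bookkeeping column is dropped.
#' @param path output path.
#' @export
write_colvar <- function(cv, path) {
  df <- as.data.frame(cv)
  df$frame <- NULL
  write_plumed_table(df, path)
}

#' @rdname write_colvar
#' @export
read_colvar <- function(path) read_plumed_table(path)

#' Write / read a bias (HILLS) history
#'
#' @param hills data.frame with columns `time`, one center and one
#'   sigma column per CV (`<cv>` and `sigma_<cv>`), `height` (kJ/mol)
#'   and `biasf`.
#' @param path file path.
#' @export
write_hills <- function(hills, path) {
  need <- c("time", "height", "biasf")
  if (!all(need %in% names(hills)))
    stop("hills table needs columns ", paste(need, collapse = ", "))
  write_plumed_table(hills, path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  df <- read_plumed_table(path)
  if (!all(c("time", "height") %in% names(df)))
    stop("not a HILLS table: ", path)
  df
}

hills_cv_names <- function(hills) {
  nm <- names(hills)
  sig <- nm[startsWith(nm, "sigma_")]
  sub("^sigma_", "", sig)
}
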