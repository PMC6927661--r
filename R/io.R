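# File formats. Coordinate convention for all delimited outputs: x = column
# index rightward, y = row index downward, origin (0, 0) at the top-left
# site; the R API itself is 1-based, so writers subtract 1 and readers add 1.

#' Read / write lattice snapshots
#'
#' Plain-text grid: one lattice row per line, whitespace-separated integer
#' spin indices. Writing then reading returns the identical matrix.
#'
#' @param path File path.
#' @return `read_lattice()` returns an integer spin matrix.
#' @export
read_lattice <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("empty lattice file: %s", path))
  rows <- lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    vals <- suppressWarnings(as.integer(toks))
    if (any(is.na(vals)))
      abort(sprintf("non-integer entry in %s at line %d", path, i))
    vals
  })
  n <- lengths(rows)
  if (length(unique(n)) != 1) {
    bad <- which(n != n[1])[1]
    abort(sprintf("ragged lattice file %s: line %d has %d entries, expected %d",
                  path, bad, n[bad], n[1]))
  }
  do.call(rbind, rows)
}

#' @param spin An integer spin matrix or a [cpm_state()].
#' @rdname read_lattice
#' @export
write_lattice <- function(spin, path) {
  if (inherits(spin, "cpm_state")) spin <- spin$spin
  lines <- apply(spin, 1, paste, collapse = " ")
  writeLines(lines, path)
  invisible(path)
}

#' Render a lattice snapshot to PNG
#'
#' One color per cell index (medium white). Requires the `png` package.
#'
#' @inheritParams write_lattice
#' @param path Output path.
#' @export
write_lattice_png <- function(spin, path) {
  if (!requireNamespace("png", quietly = TRUE))
    abort("the 'png' package is required for PNG export")
  if (inherits(spin, "cpm_state")) spin <- spin$spin
  n <- max(spin)
  cols <- c("#FFFFFF", grDevices::hcl(h = seq(15, 375, length.out = n + 1)[seq_len(n)],
                                      c = 80, l = 60))
  rgbv <- grDevices::col2rgb(cols[spin + 1]) / 255
  img <- array(0, dim = c(nrow(spin), ncol(spin), 3))
  img[, , 1] <- matrix(rgbv[1, ], nrow(spin), ncol(spin))
  img[, , 2] <- matrix(rgbv[2, ], nrow(spin), ncol(spin))
  img[, , 3] <- matrix(rgbv[3, ], nrow(spin), ncol(spin))
  png::writePNG(img, path)
  invisible(path)
}

#' Read / write force tables
#'
#' Tab-separated tables with header `x y cell_id fx fy`; coordinates are
#' written 0-based (see the package README), forces with 9+ significant
#' digits so that round trips preserve every vector.
#'
#' @param path File path.
#' @return `read_force_table()` returns a force table (1-based coordinates).
#' @export
read_force_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "numeric")
  need <- c("x", "y", "cell_id", "fx", "fy")
  if (!all(need %in% names(d)))
    abort(sprintf("force table %s lacks columns: %s", path,
                  paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d[, c("x", "y")]))
    abort(sprintf("force table %s has duplicate site keys", path))
  new_cpm_forces(tibble(x = d$x + 1, y = d$y + 1,
                        cell_id = as.integer(d$cell_id),
                        fx = d$fx, fy = d$fy,
                        weight = if ("weight" %in% names(d)) d$weight else 0))
}

#' @param forces A force table.
#' @rdname read_force_table
#' @export
write_force_table <- function(forces, path) {
  hdr <- "x\ty\tcell_id\tfx\tfy\tweight"
  lines <- sprintf("%d\t%d\t%d\t%.10g\t%.10g\t%.10g",
                   as.integer(forces$x - 1), as.integer(forces$y - 1),
                   as.integer(forces$cell_id), forces$fx, forces$fy,
                   if (is.null(forces$weight)) rep(0, nrow(forces)) else forces$weight)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read / write chemical-field snapshots
#'
#' Same grid layout as lattice snapshots but with real-valued entries; `u`
#' and `v` are stored as a pair of files.
#'
#' @param path File path of one component.
#' @return `read_chem_matrix()` returns a numeric matrix.
#' @export
read_chem_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("empty field file: %s", path))
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  if (length(unique(lengths(rows))) != 1)
    abort(sprintf("ragged field file: %s", path))
  do.call(rbind, rows)
}

#' @param q A numeric matrix.
#' @rdname read_chem_matrix
#' @export
write_chem_matrix <- function(q, path) {
  writeLines(apply(q, 1, function(r) paste(sprintf("%.10g", r), collapse = " ")),
             path)
  invisible(path)
}

#' Read / write flat key-value run configurations
#'
#' One `key = value` pair per line; `#` starts a comment. Values that parse
#' as numbers become numeric, everything else stays character. Keys follow
#' the Hamiltonian symbols (`lambda_a`, `rest_area`, `rest_perimeter`,
#' `temperature`, `yield`, `radius`, `xi`, `J.0.1`, ...).
#'
#' @param path File path.
#' @return `read_run_config()` returns a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config file: %s", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "=", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      abort(sprintf("malformed config line %d in %s: %s", i, path, lines[[i]]))
    key <- trimws(parts[1]); val <- trimws(parts[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @param config A named list.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, if (is.numeric(v)) sprintf("%.10g", v) else as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
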