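#' Read digitized wing geometry from CSV
#'
#' The file dialect mirrors the deposited digitization tables: pixel
#' coordinates with the image origin at the top-left corner, X increasing
#' rightward (proximal) and Y increasing downward, one row per vertex, and
#' a starting-node column in which `1` marks the first vertex of each
#' polyline. The margin and the ridge peaks may live in one file
#' distinguished by a feature column (values `margin` / `ridge`), or in
#' two files (`path` = margin, `ridges_path` = ridges). On ingest,
#' coordinates are converted to micrometres and the Y axis is flipped to
#' point up, so that angles measured counter-clockwise from positive X are
#' ordinary cartesian angles.
#'
#' Column names are configurable through `col_map` and matched
#' case-insensitively; a UTF-8 byte-order mark and trailing blank lines
#' are tolerated.
#'
#' @param path CSV of the margin (or of margin + ridges when it has a
#'   feature column).
#' @param ridges_path Optional second CSV holding the ridge polylines.
#' @param scale Micrometres per pixel; default 56/75.
#' @param col_map Named list mapping the roles `x`, `y`, `starting_node`,
#'   `feature` to column names in the file.
#' @return A [wing_geometry()].
#' @export
read_geometry_csv <- function(path, ridges_path = NULL,
                              scale = DEFAULT_SCALE_UM_PER_PX,
                              col_map = list()) {
  cm <- modifyList(list(x = "X", y = "Y", starting_node = "starting_node",
                        feature = "feature"), col_map)
  raw <- read_csv_strict(path)
  x <- pick_col(raw, cm$x, path)
  has_feature <- tolower(cm$feature) %in% tolower(names(raw))

  if (!is.null(ridges_path)) {
    margin_rows <- raw
    ridge_rows <- read_csv_strict(ridges_path)
  } else if (has_feature) {
    feat <- tolower(trimws(pick_col(raw, cm$feature, path, numeric = FALSE)))
    if (!all(feat %in% c("margin", "ridge"))) {
      abort(sprintf("file %s: feature column must contain only 'margin'/'ridge'.",
                    path))
    }
    margin_rows <- raw[feat == "margin", ]
    ridge_rows <- raw[feat == "ridge", ]
  } else {
    abort(sprintf(
      "file %s: no '%s' column and no `ridges_path`; cannot tell margin from ridges.",
      path, cm$feature))
  }
  if (nrow(margin_rows) == 0L) abort(sprintf("file %s: no margin rows.", path))

  margin_lines <- split_polylines(margin_rows, cm, path, scale)
  if (length(margin_lines) != 1L) {
    abort(sprintf("file %s: expected exactly one margin polyline, found %d.",
                  path, length(margin_lines)))
  }
  ridge_lines <- split_polylines(ridge_rows, cm,
                                 ridges_path %||% path, scale)
  ridges <- purrr::imap_dfr(ridge_lines, function(df, i) {
    dplyr::mutate(df, ridge = as.integer(i), .before = 1)
  })
  wing_geometry(margin_lines[[1]], ridges, scale = scale)
}

# split rows into polylines at starting_node == 1; convert px -> um, flip Y
split_polylines <- function(rows, cm, path, scale) {
  if (nrow(rows) == 0L) return(list())
  x <- pick_col(rows, cm$x, path)
  y <- pick_col(rows, cm$y, path)
  sn <- pick_col(rows, cm$starting_node, path)
  if (!sn[1] %in% 1) {
    abort(sprintf("file %s: first vertex of a block must have %s = 1 (row 1).",
                  path, cm$starting_node))
  }
  grp <- cumsum(sn %in% 1)
  lines <- lapply(split(seq_along(x), grp), function(idx) {
    if (length(idx) < 2L) {
      abort(sprintf("file %s: polyline starting at row %d has < 2 points.",
                    path, idx[1]))
    }
    tibble(x = x[idx] * scale, y = -y[idx] * scale)
  })
  unname(lines)
}

#' Write wing geometry to CSV
#'
#' Emits the same dialect [read_geometry_csv()] reads: pixel coordinates
#' (Y down), a starting-node flag, and a feature column, in one file.
#'
#' @param geom A [wing_geometry()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_geometry_csv <- function(geom, path) {
  stopifnot(inherits(geom, "wing_geometry"))
  s <- geom$scale
  m <- tibble(X = geom$margin$x / s, Y = -geom$margin$y / s,
              starting_node = c(1L, rep(0L, nrow(geom$margin) - 1L)),
              feature = "margin")
  r <- geom$ridges |>
    dplyr::group_by(.data$ridge) |>
    dplyr::mutate(starting_node = as.integer(dplyr::row_number() == 1L)) |>
    dplyr::ungroup() |>
    dplyr::transmute(X = .data$x / s, Y = -.data$y / s,
                     .data$starting_node, feature = "ridge")
  readr::write_csv(dplyr::bind_rows(m, r), path)
  invisible(path)
}

#' Read quadrat centres / hair orientations from CSV
#'
#' `read_quadrats_csv()` reads quadrat centre pixel coordinates (same
#' image convention as [read_geometry_csv()]) and converts them to
#' micrometres with Y up. `read_orientations_csv()` reads one row per
#' measured hair: the quadrat id and the hair's orientation `phi` in
#' degrees, a standard cartesian angle from the positive X axis (no
#' conversion needed). Angles outside `[-360, 360]` are rejected, as are
#' duplicate `(quadrat, hair)` rows when a hair id column is present.
#'
#' @param path CSV path.
#' @param scale Micrometres per pixel.
#' @param col_map Named list mapping roles (`quadrat`, `x`, `y` or
#'   `quadrat`, `phi`, `hair`) to file column names.
#' @return A tibble: `quadrat`, `x`, `y` (um) or `quadrat`, `phi_deg`.
#' @export
read_quadrats_csv <- function(path, scale = DEFAULT_SCALE_UM_PER_PX,
                              col_map = list()) {
  cm <- modifyList(list(quadrat = "quadrat", x = "X", y = "Y"), col_map)
  raw <- read_csv_strict(path)
  out <- tibble(
    quadrat = pick_col(raw, cm$quadrat, path),
    x = pick_col(raw, cm$x, path) * scale,
    y = -pick_col(raw, cm$y, path) * scale
  )
  if (anyDuplicated(out$quadrat)) {
    abort(sprintf("file %s: duplicate quadrat ids.", path))
  }
  out
}

#' @rdname read_quadrats_csv
#' @export
read_orientations_csv <- function(path, col_map = list()) {
  cm <- modifyList(list(quadrat = "quadrat", phi = "phi", hair = "hair"),
                   col_map)
  raw <- read_csv_strict(path)
  phi <- pick_col(raw, cm$phi, path)
  bad <- which(abs(phi) > 360)
  if (length(bad)) {
    abort(sprintf("file %s: angle out of [-360, 360] at data row(s) %s.",
                  path, paste(bad, collapse = ", ")))
  }
  out <- tibble(quadrat = pick_col(raw, cm$quadrat, path), phi_deg = phi)
  if (tolower(cm$hair) %in% tolower(names(raw))) {
    hair <- pick_col(raw, cm$hair, path)
    if (anyDuplicated(cbind(out$quadrat, hair))) {
      abort(sprintf("file %s: duplicate (quadrat, hair) rows.", path))
    }
  }
  out
}

#' @rdname read_quadrats_csv
#' @param centres,orientations Tibbles as returned by the readers.
#' @export
write_quadrats_csv <- function(centres, path,
                               scale = DEFAULT_SCALE_UM_PER_PX) {
  readr::write_csv(tibble(quadrat = centres$quadrat,
                          X = centres$x / scale, Y = -centres$y / scale),
                   path)
  invisible(path)
}

#' @rdname read_quadrats_csv
#' @export
write_orientations_csv <- function(orientations, path) {
  readr::write_csv(tibble(quadrat = orientations$quadrat,
                          phi = orientations$phi_deg), path)
  invisible(path)
}

#' Read and assemble a full quadrat dataset
#'
#' Convenience wrapper: reads quadrat centres and hair orientations and
#' joins them against a geometry into the canonical quadrat table.
#'
#' @param quadrats_path,orientations_path CSV paths.
#' @param geom A [wing_geometry()].
#' @param scale Micrometres per pixel.
#' @return A quadrat tibble (see [quadrat_samples()]).
#' @export
read_quadrat_data <- function(quadrats_path, orientations_path, geom,
                              scale = DEFAULT_SCALE_UM_PER_PX) {
  quadrat_samples(read_quadrats_csv(quadrats_path, scale = scale),
                  read_orientations_csv(orientations_path),
                  geom)
}

# -- strict CSV helpers -------------------------------------------------

# read as character, drop blank lines; BOM handled by readr
read_csv_strict <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)
  if (nrow(raw) > 0L) {
    blank <- apply(is.na(raw) | raw == "", 1, all)
    raw <- raw[!blank, ]
  }
  if (nrow(raw) == 0L) abort(sprintf("file %s: no data rows.", path))
  raw
}

# fetch a column by case-insensitive name; parse numerics with row-numbered
# errors
pick_col <- function(raw, name, path, numeric = TRUE) {
  hit <- which(tolower(names(raw)) == tolower(name))
  if (length(hit) != 1L) {
    abort(sprintf("file %s: missing required column '%s' (found: %s).",
                  path, name, paste(names(raw), collapse = ", ")))
  }
  v <- raw[[hit]]
  if (!numeric) return(v)
  num <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(num))
  if (length(bad)) {
    abort(sprintf("file %s: non-numeric '%s' at data row(s) %s.",
                  path, name, paste(bad, collapse = ", ")))
  }
  num
}
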