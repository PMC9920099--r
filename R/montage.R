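# Electrode grid layouts and the short-distance spatial filter. A montage
# places each electrode on a (row, sagittal-line) grid; connections between
# grid 8-neighbours are considered volume-conduction suspects and removed,
# except across the two lines flanking the midline (lines 1 and 2), which
# are kept because they span the inter-hemispheric divide.

#' Load an electrode grid layout from JSON
#'
#' The JSON must contain `rows` (ordered row labels, anterior to
#' posterior), `lines` (ordered sagittal line numbers, left to right) and
#' `electrodes` (a name -> `{row, line}` mapping). Grid coordinates are
#' the positions of the electrode's row and line in those orderings.
#'
#' @param path path to a montage JSON file; the default is the built-in
#'   24-electrode sensorimotor montage (rows FC, C, CP, P; lines 5, 3, 1,
#'   2, 4, 6).
#' @return an object of class `montage`: data.frame with columns `name`,
#'   `row`, `line`, `grid_row`, `grid_col`.
#' @export
load_montage <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "montage_24.json",
                        package = "netparafac", mustWork = TRUE)
  spec <- jsonlite::fromJSON(path)
  if (!all(c("rows", "lines", "electrodes") %in% names(spec)))
    stop("montage JSON must define 'rows', 'lines' and 'electrodes'")
  nm <- names(spec$electrodes)
  if (anyDuplicated(nm))
    stop("duplicate electrode name: ", nm[duplicated(nm)][1L])
  lay <- data.frame(
    name = nm,
    row = vapply(spec$electrodes, function(e) as.character(e$row), ""),
    line = vapply(spec$electrodes, function(e) as.numeric(e$line), 0),
    stringsAsFactors = FALSE)
  rownames(lay) <- NULL
  lay$grid_row <- match(lay$row, spec$rows)
  lay$grid_col <- match(lay$line, spec$lines)
  if (anyNA(lay$grid_row) || anyNA(lay$grid_col))
    stop("electrode with row/line not listed in 'rows'/'lines': ",
         paste(lay$name[is.na(lay$grid_row) | is.na(lay$grid_col)],
               collapse = ", "))
  coord <- paste(lay$grid_row, lay$grid_col)
  if (anyDuplicated(coord))
    stop("duplicate grid coordinate for electrodes: ",
         paste(lay$name[coord %in% coord[duplicated(coord)]],
               collapse = ", "))
  class(lay) <- c("montage", "data.frame")
  lay
}

#' Remove short-distance connections between adjacent electrodes
#'
#' Zeroes entries (i, j) and (j, i) whenever electrodes i and j are
#' 8-neighbours on the montage grid (Chebyshev distance 1 in grid
#' coordinates), unless one lies on sagittal line 1 and the other on line
#' 2 (the pair spanning the midline, which is retained). All other
#' entries are unchanged. This suppresses spurious local connections due
#' to volume conduction before group-level factorization.
#'
#' @param mat K x K connectivity matrix whose rownames are electrode
#'   names present in the montage.
#' @param montage a `montage` object from [load_montage()] (default: the
#'   built-in 24-electrode layout).
#' @return the filtered matrix.
#' @export
spatial_filter <- function(mat, montage = load_montage()) {
  mat <- as.matrix(mat)
  nodes <- rownames(mat)
  if (is.null(nodes))
    stop("mat must carry electrode names as rownames")
  pos <- match(nodes, montage$name)
  if (anyNA(pos))
    stop("electrode(s) missing from montage: ",
         paste(nodes[is.na(pos)], collapse = ", "))
  gr <- montage$grid_row[pos]
  gc <- montage$grid_col[pos]
  ln <- montage$line[pos]
  K <- nrow(mat)
  for (i in seq_len(K - 1L)) {
    for (j in seq.int(i + 1L, K)) {
      cheb <- max(abs(gr[i] - gr[j]), abs(gc[i] - gc[j]))
      midline_pair <- (ln[i] == 1 && ln[j] == 2) || (ln[i] == 2 && ln[j] == 1)
      if (cheb == 1L && !midline_pair) {
        mat[i, j] <- 0
        mat[j, i] <- 0
      }
    }
  }
  mat
}
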