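python_binary <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found on PATH", call. = FALSE)
  py
}

hull_script <- function() {
  p <- system.file("python", "hull_volume.py", package = "benthovuln")
  if (!nzchar(p)) {
    # package loaded via pkgload during development
    p <- file.path("inst", "python", "hull_volume.py")
  }
  p
}

#' Convex-hull volumes for a batch of point sets
#'
#' Computes the exact m-dimensional convex-hull (quickhull) volume for each
#' point set in one Qhull call batch. A set with fewer than m+1 points, or
#' an affinely dependent one, is degenerate: volume 0 with `degenerate =
#' TRUE` rather than a lower-dimensional measure.
#'
#' All volume computations in the package route through this batch form so
#' that resampling (thousands of hulls) stays cheap.
#'
#' @param point_list A list of numeric matrices (rows = points, columns =
#'   coordinates; all matrices finite, m >= 2).
#' @return A data.frame with columns `volume` and `degenerate`.
#' @export
hull_volumes <- function(point_list) {
  stopifnot(is.list(point_list), length(point_list) >= 1L)
  for (p in point_list) {
    if (!is.matrix(p) || ncol(p) < 2L) {
      stop("each point set must be a matrix with at least 2 columns",
           call. = FALSE)
    }
    if (!all(is.finite(p))) stop("non-finite coordinates", call. = FALSE)
  }
  fin <- tempfile(fileext = ".txt")
  on.exit(unlink(fin), add = TRUE)
  con <- file(fin, open = "wt")
  writeLines(as.character(length(point_list)), con)
  for (p in point_list) {
    writeLines(paste(nrow(p), ncol(p)), con)
    utils::write.table(format(p, digits = 17, scientific = TRUE, trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  close(con)
  out <- suppressWarnings(
    system2(python_binary(), c(shQuote(hull_script()), shQuote(fin)),
            stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("hull volume computation failed:\n", paste(out, collapse = "\n"),
         call. = FALSE)
  }
  parts <- do.call(rbind, strsplit(out, " ", fixed = TRUE))
  data.frame(volume = as.numeric(parts[, 1]),
             degenerate = parts[, 2] == "1")
}

#' Convex-hull volume of one point set
#'
#' @param points Numeric matrix, rows = points, columns = coordinates
#'   (m >= 2).
#' @return A list with `volume` and `degenerate`.
#' @seealso [hull_volumes()] for batches.
#' @export
hull_volume <- function(points) {
  res <- hull_volumes(list(points))
  list(volume = res$volume[1], degenerate = res$degenerate[1])
}
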