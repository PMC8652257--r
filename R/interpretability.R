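# From routing coupling coefficients to per-class data-source importance:
# type-average matrices, effective rows, the overall heatmap, repeat
# averaging and top-k rankings.

#' Per-class average coupling matrices
#'
#' For each class, the element-wise mean of the coupling matrices of that
#' class's samples, transposed to k x l (rows = type capsules, columns =
#' primary capsules / sources). Because each sample's couplings are a
#' per-source softmax over classes, every column of every per-class average
#' still sums to 1.
#'
#' @param couplings An N x l x k array of per-sample coupling coefficients
#'   (as returned by [caps_forward()]), or a `caps_model` together with
#'   `data`.
#' @param labels Integer class labels in `1..k` (or taken from `data`).
#' @param class_names Character class names; defaults to the coupling
#'   array's dimnames or `class_1..k`.
#' @param data Optional [modular_dataset()]; when `couplings` is a model the
#'   couplings are recomputed in inference mode on this data.
#' @return Object of class `caps_type_average`: `matrices` (named list of
#'   k x l matrices), `counts` (samples per class), `sources`, `classes`.
#'   Classes with zero samples are omitted with a warning.
#' @export
type_average_coupling <- function(couplings, labels = NULL,
                                  class_names = NULL, data = NULL) {
  if (inherits(couplings, "caps_model")) {
    if (is.null(data)) stop("supply `data` to extract couplings from a model")
    fw <- caps_forward(couplings, data)
    class_names <- couplings$class_names
    if (is.null(labels)) labels <- data$labels
    couplings <- fw$couplings
  }
  stopifnot(length(dim(couplings)) == 3L)
  if (is.null(labels)) stop("labels are required")
  k <- dim(couplings)[3L]
  l <- dim(couplings)[2L]
  if (is.null(class_names))
    class_names <- dimnames(couplings)[[3L]] %||% paste0("class_", seq_len(k))
  srcs <- dimnames(couplings)[[2L]] %||% paste0("source_", seq_len(l))
  labels <- as.integer(labels)
  mats <- list()
  counts <- integer(0)
  for (t in seq_len(k)) {
    idx <- which(labels == t)
    if (length(idx) == 0L) {
      warning("class '", class_names[t], "' has no samples; omitted")
      next
    }
    # mean over samples of the k x l (transposed) coupling matrix
    m <- apply(couplings[idx, , , drop = FALSE], c(2L, 3L), mean)
    m <- t(m)                       # k x l: rows type capsules, cols sources
    dimnames(m) <- list(type_capsule = class_names, source = srcs)
    mats[[class_names[t]]] <- m
    counts[class_names[t]] <- length(idx)
  }
  structure(list(matrices = mats, counts = counts, sources = srcs,
                 classes = names(mats)),
            class = "caps_type_average")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the overall heatmap from per-class averages
#'
#' Row t of the overall heatmap is the "effective type capsule row" of class
#' t's average coupling matrix: the row whose type-capsule index equals the
#' class itself. Its entries are the source importance scores for that
#' class. The operation is a pure projection; values are never mixed across
#' classes.
#'
#' @param averages A `caps_type_average`.
#' @return Object of class `caps_heatmap` wrapping a k x l matrix with class
#'   rownames and source colnames.
#' @export
overall_heatmap <- function(averages) {
  stopifnot(inherits(averages, "caps_type_average"))
  mats <- averages$matrices
  shapes <- vapply(mats, function(m) paste(dim(m), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L)
    stop("per-class average matrices disagree on shape: ",
         paste(unique(shapes), collapse = " vs "))
  cls <- averages$classes
  out <- t(vapply(cls, function(cn) mats[[cn]][cn, ],
                  numeric(length(averages$sources))))
  out <- matrix(out, nrow = length(cls),
                dimnames = list(class = cls, source = averages$sources))
  structure(list(matrix = out, classes = cls, sources = averages$sources),
            class = "caps_heatmap")
}

#' @export
print.caps_heatmap <- function(x, ...) {
  cat(sprintf("<caps_heatmap> %d classes x %d sources\n",
              length(x$classes), length(x$sources)))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Average overall heatmaps across training repeats
#'
#' Element-wise mean of identically shaped and labeled heatmaps; label-order
#' mismatches are an error (no silent realignment).
#'
#' @param heatmaps A list of `caps_heatmap` objects (length >= 1).
#' @return A `caps_heatmap`.
#' @export
average_over_repeats <- function(heatmaps) {
  stopifnot(length(heatmaps) >= 1L,
            all(vapply(heatmaps, inherits, logical(1), "caps_heatmap")))
  ref <- heatmaps[[1L]]
  for (h in heatmaps[-1L]) {
    if (!identical(h$classes, ref$classes) ||
        !identical(h$sources, ref$sources))
      stop("heatmaps disagree on class/source labels or order")
  }
  m <- Reduce(`+`, lapply(heatmaps, `[[`, "matrix")) / length(heatmaps)
  structure(list(matrix = m, classes = ref$classes, sources = ref$sources),
            class = "caps_heatmap")
}

#' Top-k most important sources per class
#'
#' Ranks each class's heatmap row descending; ties broken by ascending
#' source index. Adding a constant to a whole row leaves the ranking
#' unchanged.
#'
#' @param heatmap A `caps_heatmap`.
#' @param k_top Number of sources to keep per class (1..l).
#' @param normalize Min-max normalize each row to `[0, 1]` before reporting
#'   (for cross-model comparison plots; ranking is unaffected).
#' @return Object of class `caps_importance`: a data frame with columns
#'   `class`, `rank`, `source`, `score`.
#' @export
top_k_sources <- function(heatmap, k_top = 10L, normalize = FALSE) {
  stopifnot(inherits(heatmap, "caps_heatmap"))
  l <- length(heatmap$sources)
  if (k_top < 1L || k_top > l)
    stop("k_top must be in 1..", l)
  rows <- lapply(heatmap$classes, function(cn) {
    sc <- heatmap$matrix[cn, ]
    if (normalize) {
      rng <- range(sc)
      sc <- if (diff(rng) == 0) sc * 0 else (sc - rng[1L]) / diff(rng)
    }
    ord <- order(-sc, seq_along(sc))[seq_len(k_top)]
    data.frame(class = cn, rank = seq_len(k_top),
               source = heatmap$sources[ord], score = unname(sc[ord]))
  })
  structure(do.call(rbind, rows), class = c("caps_importance", "data.frame"))
}

#' Overlap fraction of two top-k rankings
#'
#' Per class, `|A intersect B| / k_top` between the top-k source sets of two
#' rankings (e.g. models trained with and without labeling-TF exclusion).
#'
#' @param a,b `caps_importance` objects over the same classes.
#' @return Named numeric vector of per-class overlap fractions in `[0, 1]`.
#' @export
ranking_overlap <- function(a, b) {
  cls <- intersect(unique(a$class), unique(b$class))
  if (length(cls) == 0L) stop("rankings share no classes")
  out <- vapply(cls, function(cn) {
    sa <- a$source[a$class == cn]
    sb <- b$source[b$class == cn]
    length(intersect(sa, sb)) / max(length(sa), length(sb))
  }, numeric(1))
  names(out) <- cls
  out
}

#' Write interpretability outputs as TSV
#'
#' `type_average_<class>.tsv` (one k x l matrix per class),
#' `overall_heatmap.tsv` (k x l) and `importance_report.tsv` (class, rank,
#' source, score), all with header rows naming sources and classes.
#'
#' @param x A `caps_type_average`, `caps_heatmap` or `caps_importance`.
#' @param dir Output directory (created if needed).
#' @param name File name for heatmaps (default `overall_heatmap.tsv`).
#' @return Paths written, invisibly.
#' @export
write_interpretability <- function(x, dir,
                                   name = "overall_heatmap.tsv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (inherits(x, "caps_type_average")) {
    for (cn in x$classes) {
      p <- file.path(dir, paste0("type_average_", gsub("[^A-Za-z0-9_.-]", "_",
                                                       cn), ".tsv"))
      utils::write.table(x$matrices[[cn]], p, sep = "\t", quote = FALSE,
                         col.names = NA)
      paths <- c(paths, p)
    }
  } else if (inherits(x, "caps_heatmap")) {
    p <- file.path(dir, name)
    utils::write.table(x$matrix, p, sep = "\t", quote = FALSE,
                       col.names = NA)
    paths <- p
  } else if (inherits(x, "caps_importance")) {
    p <- file.path(dir, "importance_report.tsv")
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- p
  } else stop("unsupported object")
  invisible(paths)
}

#' Read an overall heatmap written by [write_interpretability()]
#'
#' @param path Path to a heatmap TSV.
#' @return A `caps_heatmap`.
#' @export
read_heatmap <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1L,
                                   check.names = FALSE))
  structure(list(matrix = m, classes = rownames(m), sources = colnames(m)),
            class = "caps_heatmap")
}

#' Render a heatmap to PNG (optional thin layer; numbers are the contract)
#'
#' @param heatmap A `caps_heatmap`.
#' @param path Output PNG path.
#' @export
plot_heatmap_png <- function(heatmap, path) {
  grDevices::png(path, width = 900, height = 400)
  on.exit(grDevices::dev.off())
  m <- heatmap$matrix
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "source", ylab = "class")
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 1,
                 cex.axis = 0.8)
  invisible(path)
}
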