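# Modular data sources: specifications, gene-set priors, and decomposition of
# an expression matrix into per-source input blocks.

#' Define a single modular data source
#'
#' A source is one block of input features that will be standardized into one
#' primary capsule: a named group of columns of a wide table, or the member
#' genes of a gene set.
#'
#' @param name Short unique label (e.g. `"Disease"`, `"Tumor_var"`, a TF
#'   symbol).
#' @param kind One of `"numeric"`, `"onehot"`, `"gene_set"`.
#' @param features Character vector of feature identifiers (column names or
#'   gene symbols), non-empty and unique within the source.
#' @return An object of class `caps_source` with fields `name`, `kind`,
#'   `features` and `length` (the number of features, the width `r_i` of the
#'   block).
#' @export
source_spec <- function(name, kind = c("numeric", "onehot", "gene_set"),
                        features) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("source name must be a single non-empty string")
  features <- as.character(features)
  if (length(features) == 0L)
    stop("source '", name, "': features must be non-empty")
  if (anyDuplicated(features))
    stop("source '", name, "': duplicated feature identifiers")
  structure(
    list(name = name, kind = kind, features = features,
         length = length(features)),
    class = "caps_source"
  )
}

#' @export
print.caps_source <- function(x, ...) {
  cat(sprintf("<caps_source> %s [%s], %d features\n", x$name, x$kind,
              x$length))
  invisible(x)
}

check_sources <- function(sources) {
  if (length(sources) < 1L) stop("need at least one source")
  if (!all(vapply(sources, inherits, logical(1), "caps_source")))
    stop("all sources must be caps_source objects")
  nms <- vapply(sources, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicated source names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  invisible(nms)
}

source_names <- function(sources) vapply(sources, `[[`, character(1), "name")
source_lengths <- function(sources) vapply(sources, `[[`, integer(1), "length")

#' The packaged variant-call source specification
#'
#' Returns the eight-group layout used for somatic variant refinement data:
#' 71 features split by provenance and attribute into the groups Disease (9,
#' one-hot cancer type), Reviewer (4, one-hot), Normal_pro (3), Normal_ref
#' (13), Normal_var (13), Tumor_pro (3), Tumor_ref (13) and Tumor_var (13).
#' Feature names come from the packaged manifest
#' (`extdata/variant_call_groups.tsv`); the manifest reproduces the published
#' group sizes with generic per-group feature identifiers, and real datasets
#' supply their own column-to-group manifest.
#'
#' @param manifest Optional path to a replacement manifest, a TSV with columns
#'   `group`, `kind`, `feature` (one row per feature, groups ordered by first
#'   appearance).
#' @return A list of eight `caps_source` objects totalling 71 features.
#' @export
build_variant_call_spec <- function(manifest = NULL) {
  if (is.null(manifest))
    manifest <- system.file("extdata", "variant_call_groups.tsv",
                            package = "modcaps", mustWork = TRUE)
  tab <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("group", "kind", "feature")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  groups <- unique(tab$group)
  lapply(groups, function(g) {
    rows <- tab[tab$group == g, , drop = FALSE]
    kind <- unique(rows$kind)
    if (length(kind) != 1L)
      stop("group '", g, "' has mixed kinds in manifest")
    source_spec(g, kind, rows$feature)
  })
}

#' A collection of gene sets used as prior knowledge
#'
#' @param sets A list of entries, each `list(label=, category=, genes=)` with
#'   `category` one of `"TF"`, `"PPI"`, `"regulon"`.
#' @return An object of class `gene_set_collection` with fields `sets` and
#'   `universe` (sorted union of all member genes).
#' @export
gene_set_collection <- function(sets) {
  if (length(sets) == 0L) stop("no gene sets")
  labels <- vapply(sets, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicated gene-set labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  for (s in sets) {
    if (length(s$genes) == 0L) stop("gene set '", s$label, "' is empty")
    if (anyDuplicated(s$genes))
      stop("gene set '", s$label, "' contains duplicated genes")
    if (!s$category %in% c("TF", "PPI", "regulon"))
      stop("gene set '", s$label, "': unknown category '", s$category, "'")
  }
  structure(
    list(sets = sets,
         universe = sort(unique(unlist(lapply(sets, `[[`, "genes"))))),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, %d genes in universe\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

resolve_category <- function(labels, category_rule) {
  if (is.null(category_rule)) return(rep("regulon", length(labels)))
  if (is.function(category_rule))
    return(vapply(labels, function(l) as.character(category_rule(l)),
                  character(1)))
  if (length(category_rule) == 1L && is.null(names(category_rule)))
    return(rep(as.character(category_rule), length(labels)))
  out <- unname(category_rule[labels])
  if (anyNA(out))
    stop("category_rule has no entry for: ",
         paste(labels[is.na(out)], collapse = ", "))
  as.character(out)
}

#' Parse gene sets from a GMT or two-column file
#'
#' Accepts the GMT dialect (tab-separated: label, description, then member
#' genes) or a two-column long format (`label<TAB>gene`, optional header).
#' One set is produced per unique label; gene order follows first occurrence
#' and duplicated (label, gene) pairs are collapsed.
#'
#' @param path Path to the gene-set file.
#' @param category_rule How to assign a category to each set label: `NULL`
#'   (all `"regulon"`), a single string, a named character vector
#'   (label -> category), or a function of the label.
#' @return A [gene_set_collection()].
#' @export
parse_gene_sets <- function(path, category_rule = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no gene sets in '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  is_gmt <- any(ncols >= 3L)
  labels <- character(0)
  genes_by_label <- list()
  start <- 1L
  if (!is_gmt) {
    # two-column long format; tolerate a header line
    hdr <- tolower(trimws(fields[[1L]]))
    if (length(hdr) >= 2L &&
        hdr[1L] %in% c("label", "set", "tf", "regulon") )
      start <- 2L
  }
  for (idx in seq(start, length(fields))) {
    f <- trimws(fields[[idx]])
    if (is_gmt) {
      genes <- f[-(1:2)]
      genes <- genes[nzchar(genes)]
      if (length(f) < 3L || length(genes) == 0L)
        stop("line ", idx, " of '", path, "': label '", f[1L],
             "' has zero genes")
      lab <- f[1L]
    } else {
      if (length(f) < 2L || !nzchar(f[2L]))
        stop("line ", idx, " of '", path, "': label '", f[1L],
             "' has zero genes")
      lab <- f[1L]
      genes <- f[2L]
    }
    if (is.null(genes_by_label[[lab]])) {
      labels <- c(labels, lab)
      genes_by_label[[lab]] <- genes
    } else {
      genes_by_label[[lab]] <- c(genes_by_label[[lab]], genes)
    }
  }
  cats <- resolve_category(labels, category_rule)
  sets <- mapply(function(lab, cat) {
    list(label = lab, category = cat,
         genes = unique(genes_by_label[[lab]]))
  }, labels, cats, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  gene_set_collection(sets)
}

#' Remove each set's labeling gene from its own member list
#'
#' Regulon-style gene sets are labeled by the transcription factor that
#' defines them; the TF's own expression can dominate the set's signal. This
#' removes the labeling symbol from its own target list wherever present.
#' Sets emptied by the removal are dropped with a warning. The operation is
#' idempotent.
#'
#' @param collection A [gene_set_collection()] whose labels are gene symbols.
#' @return A filtered `gene_set_collection`.
#' @export
exclude_labeling_tf <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  out <- lapply(collection$sets, function(s) {
    s$genes <- setdiff(s$genes, s$label)
    s
  })
  empty <- vapply(out, function(s) length(s$genes) == 0L, logical(1))
  if (any(empty)) {
    warning("dropping ", sum(empty),
            " gene set(s) emptied by labeling-TF removal: ",
            paste(vapply(out[empty], `[[`, character(1), "label"),
                  collapse = ", "))
    out <- out[!empty]
    if (length(out) == 0L) stop("all gene sets emptied by removal")
  }
  gene_set_collection(out)
}

#' Bundle per-source blocks into a modular dataset
#'
#' @param sources List of [source_spec()] objects.
#' @param blocks List of numeric matrices, one per source, row-aligned across
#'   sources; block `i` must have exactly `sources[[i]]$length` columns.
#' @param labels Optional per-sample class membership: an integer vector in
#'   `1..k`, or a factor/character vector matched against `class_names`.
#' @param class_names Optional character vector of class names; derived from
#'   `labels` when omitted.
#' @return An object of class `modular_dataset`.
#' @export
modular_dataset <- function(sources, blocks, labels = NULL,
                            class_names = NULL) {
  check_sources(sources)
  if (length(blocks) != length(sources))
    stop("need one block per source (", length(sources), "), got ",
         length(blocks))
  blocks <- lapply(blocks, function(b) as.matrix(b))
  ns <- unique(vapply(blocks, nrow, integer(1)))
  if (length(ns) != 1L)
    stop("blocks disagree on sample count: ", paste(ns, collapse = ", "))
  for (i in seq_along(sources)) {
    if (ncol(blocks[[i]]) != sources[[i]]$length)
      stop("block for source '", sources[[i]]$name, "' has ",
           ncol(blocks[[i]]), " columns, expected ", sources[[i]]$length)
  }
  if (!is.null(labels)) {
    if (is.factor(labels) || is.character(labels)) {
      labels <- as.factor(labels)
      if (is.null(class_names)) class_names <- levels(labels)
      labels <- match(as.character(labels), class_names)
      if (anyNA(labels)) stop("labels contain classes absent from class_names")
    } else {
      labels <- as.integer(labels)
      if (is.null(class_names))
        class_names <- paste0("class_", seq_len(max(labels)))
    }
    if (length(labels) != ns)
      stop("labels length (", length(labels), ") != sample count (", ns, ")")
    if (any(labels < 1L) || any(labels > length(class_names)))
      stop("labels reference classes outside 1..", length(class_names))
  }
  structure(
    list(sources = sources, blocks = blocks, labels = labels,
         class_names = class_names),
    class = "modular_dataset"
  )
}

#' @export
print.modular_dataset <- function(x, ...) {
  cat(sprintf("<modular_dataset> %d samples, %d sources (%d features)%s\n",
              nrow(x$blocks[[1L]]), length(x$sources),
              sum(source_lengths(x$sources)),
              if (is.null(x$labels)) ", unlabeled"
              else sprintf(", %d classes", length(x$class_names))))
  invisible(x)
}

n_samples <- function(dataset) nrow(dataset$blocks[[1L]])

#' Decompose an expression matrix into per-gene-set blocks
#'
#' Each gene set becomes one source whose block holds the expression of its
#' member genes, columns ordered as in the set. A gene absent from the matrix
#' contributes a column of zeros (the model still builds; sets with no gene
#' present produce an all-zero block with a warning). Genes belonging to
#' several sets are copied into every containing block, so each primary
#' capsule sees its own copy.
#'
#' @param matrix A samples x genes numeric matrix with gene names as column
#'   names.
#' @param sets A [gene_set_collection()].
#' @param case_insensitive Fold case on both sides when matching gene symbols
#'   (default off: exact, case-sensitive matching).
#' @param log1p Apply `log1p` to the expression values first (default off).
#' @return A [modular_dataset()] with `gene_set` sources and no labels.
#' @export
decompose_expression <- function(matrix, sets, case_insensitive = FALSE,
                                 log1p = FALSE) {
  stopifnot(inherits(sets, "gene_set_collection"))
  matrix <- as.matrix(matrix)
  if (is.null(colnames(matrix)))
    stop("expression matrix must have gene names as column names")
  if (log1p) matrix <- base::log1p(matrix)
  colkey <- if (case_insensitive) tolower(colnames(matrix)) else
    colnames(matrix)
  n <- nrow(matrix)
  sources <- vector("list", length(sets$sets))
  blocks <- vector("list", length(sets$sets))
  for (i in seq_along(sets$sets)) {
    s <- sets$sets[[i]]
    genekey <- if (case_insensitive) tolower(s$genes) else s$genes
    idx <- match(genekey, colkey)
    block <- base::matrix(0, nrow = n, ncol = length(s$genes),
                          dimnames = list(rownames(matrix), s$genes))
    hit <- !is.na(idx)
    if (any(hit)) block[, hit] <- matrix[, idx[hit], drop = FALSE]
    else warning("gene set '", s$label,
                 "': no member gene found in the matrix; block is all-zero")
    sources[[i]] <- source_spec(s$label, "gene_set", s$genes)
    blocks[[i]] <- block
  }
  modular_dataset(sources, blocks)
}

#' Attach labels to an unlabeled modular dataset
#'
#' @param dataset A [modular_dataset()].
#' @param labels,class_names As in [modular_dataset()].
#' @return The labeled dataset.
#' @export
set_labels <- function(dataset, labels, class_names = NULL) {
  modular_dataset(dataset$sources, dataset$blocks, labels, class_names)
}
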