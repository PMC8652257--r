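# Seeded synthetic modular datasets with known ground-truth source
# importance. Signal is a Gaussian mean shift (numeric sources) or a
# class-linked category (one-hot sources): the generator tests mechanism —
# can the model find planted informative sources — not scRNA realism.

#' Declare a synthetic source
#'
#' @param kind `"numeric"`, `"onehot"` or `"gene_set"`.
#' @param length Number of features in the source.
#' @param informative_for Integer class indices (1-based) for which this
#'   source carries signal; empty for pure-noise sources.
#' @param name Optional source name.
#' @return A list consumed by [synth_config()].
#' @export
synth_source <- function(kind = c("numeric", "onehot", "gene_set"),
                         length, informative_for = integer(0), name = NULL) {
  kind <- match.arg(kind)
  stopifnot(length >= 1L)
  list(kind = kind, length = as.integer(length),
       informative_for = as.integer(informative_for), name = name)
}

#' Synthetic-data configuration
#'
#' Defaults state the simulated world once: mean shift `delta = 2`, noise
#' `sigma = 1`, one-hot fidelity `p_onehot = 0.9`. Setting `delta = 0`
#' switches off ALL planted signal (numeric and one-hot alike), which is the
#' null-control configuration.
#'
#' @param n_samples Total samples; class sizes are balanced to within one.
#' @param k Number of classes.
#' @param sources List of [synth_source()] entries.
#' @param delta Mean shift added to informative numeric features for their
#'   linked class (default 2).
#' @param sigma Gaussian noise standard deviation (default 1).
#' @param p_onehot Probability that an informative one-hot source fires its
#'   class-linked category (default 0.9); must exceed 1/k.
#' @param seed Integer seed; the generated dataset is a pure function of the
#'   config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_samples, k, sources, delta = 2, sigma = 1,
                         p_onehot = 0.9, seed = 1L) {
  problems <- character(0)
  if (n_samples < 2L * k) problems <- c(problems, "n_samples < 2 * k")
  if (k < 2L) problems <- c(problems, "k < 2")
  if (delta < 0) problems <- c(problems, "delta < 0")
  if (sigma <= 0) problems <- c(problems, "sigma <= 0")
  if (p_onehot <= 1 / k || p_onehot > 1)
    problems <- c(problems, "p_onehot outside (1/k, 1]")
  if (length(sources) < 1L) problems <- c(problems, "no sources")
  covered <- sort(unique(unlist(lapply(sources, `[[`, "informative_for"))))
  if (delta > 0 && !all(seq_len(k) %in% covered))
    problems <- c(problems,
                  "every class needs at least one informative source")
  if (length(problems) > 0L)
    stop("invalid synthetic config: ", paste(problems, collapse = "; "))
  for (i in seq_along(sources))
    if (is.null(sources[[i]]$name))
      sources[[i]]$name <- sprintf("S%02d_%s", i, sources[[i]]$kind)
  structure(list(n_samples = as.integer(n_samples), k = as.integer(k),
                 sources = sources, delta = delta, sigma = sigma,
                 p_onehot = p_onehot, seed = as.integer(seed)),
            class = "synth_config")
}

balanced_labels <- function(n, k) sample(sort(rep_len(seq_len(k), n)))

#' Generate a modular dataset with planted source importance
#'
#' Numeric blocks are `Normal(0, sigma^2)` noise; features of a source
#' informative for class t get a `+delta` mean for samples of class t.
#' One-hot blocks fire category `((t - 1) mod length) + 1` with probability
#' `p_onehot` for samples of their linked classes, otherwise a uniform
#' category. With `delta = 0` no source is informative. Fully determined by
#' the config seed; labels are balanced to within one sample per class.
#'
#' @param cfg A [synth_config()].
#' @return List with `dataset` (a labeled [modular_dataset()]) and `truth`
#'   (class `synth_truth`: `informative`, a k x l logical matrix, and
#'   `shift`, the planted mean shift).
#' @export
generate_modular <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  k <- cfg$k
  labels <- balanced_labels(n, k)
  any_signal <- cfg$delta > 0
  l <- length(cfg$sources)
  informative <- matrix(FALSE, k, l,
                        dimnames = list(class = paste0("class_", seq_len(k)),
                                        source = vapply(cfg$sources, `[[`,
                                                        character(1), "name")))
  specs <- vector("list", l)
  blocks <- vector("list", l)
  for (i in seq_len(l)) {
    src <- cfg$sources[[i]]
    feats <- sprintf("%s_f%02d", src$name, seq_len(src$length))
    spec_kind <- if (src$kind == "gene_set") "gene_set" else src$kind
    specs[[i]] <- source_spec(src$name, spec_kind, feats)
    linked <- if (any_signal) src$informative_for else integer(0)
    informative[linked, i] <- TRUE
    if (src$kind == "onehot") {
      block <- matrix(0, n, src$length)
      cat_idx <- integer(n)
      for (t in seq_len(k)) {
        idx <- which(labels == t)
        if (t %in% linked) {
          hot <- ((t - 1L) %% src$length) + 1L
          fire <- stats::runif(length(idx)) < cfg$p_onehot
          cat_idx[idx[fire]] <- hot
          others <- setdiff(seq_len(src$length), hot)
          if (src$length == 1L) cat_idx[idx[!fire]] <- 1L
          else cat_idx[idx[!fire]] <-
              others[sample.int(length(others), sum(!fire), replace = TRUE)]
        } else {
          cat_idx[idx] <- sample.int(src$length, length(idx),
                                     replace = TRUE)
        }
      }
      block[cbind(seq_len(n), cat_idx)] <- 1
    } else {
      block <- matrix(stats::rnorm(n * src$length, 0, cfg$sigma), n,
                      src$length)
      for (t in linked)
        block[labels == t, ] <- block[labels == t, ] + cfg$delta
    }
    colnames(block) <- feats
    blocks[[i]] <- block
  }
  dataset <- modular_dataset(specs, blocks, labels,
                             paste0("class_", seq_len(k)))
  truth <- structure(list(informative = informative, shift = cfg$delta),
                     class = "synth_truth")
  list(dataset = dataset, truth = truth)
}

#' The eight-group variant-call-like synthetic layout
#'
#' Mirrors the packaged variant-call source specification: two one-hot
#' sources of lengths 9 and 4 and six numeric sources of lengths 3, 13, 13,
#' 3, 13, 13 (71 features total) over three classes. Informative sources are
#' assigned round-robin so that every class has at least one.
#'
#' @param n_samples,seed,delta,sigma Passed to [synth_config()].
#' @return A [synth_config()].
#' @export
variant_call_like_config <- function(n_samples = 2000L, seed = 1L,
                                     delta = 2, sigma = 1) {
  lens <- c(9L, 4L, 3L, 13L, 13L, 3L, 13L, 13L)
  kinds <- c("onehot", "onehot", rep("numeric", 6L))
  nms <- c("Disease", "Reviewer", "Normal_pro", "Normal_ref", "Normal_var",
           "Tumor_pro", "Tumor_ref", "Tumor_var")
  k <- 3L
  sources <- lapply(seq_along(lens), function(i)
    synth_source(kinds[i], lens[i],
                 informative_for = ((i - 1L) %% k) + 1L, name = nms[i]))
  synth_config(n_samples, k, sources, delta = delta, sigma = sigma,
               seed = seed)
}

#' Generate an expression matrix with gene-set priors and planted signal
#'
#' Emulates the prior-knowledge pipeline: a cells x genes matrix plus
#' regulon-like gene sets. Each set draws `ceiling(genes_per_set * (1 -
#' overlap_fraction))` private genes from a disjoint pool and the remainder
#' from the whole universe (so sets may overlap). Per class,
#' `relevant_per_class` sets are designated relevant and their member genes
#' are up-shifted by `delta` in that class. Expression is a rectified
#' Gaussian, `max(0, Normal(mu, sigma^2))`, keeping values non-negative
#' without a count-model dependency. Each set is labeled by a distinct
#' "TF" gene symbol, included in its own target list with probability
#' `label_in_set_prob` (so labeling-TF exclusion has work to do).
#'
#' @param n_genes Universe size (default 500).
#' @param n_sets Number of gene sets (default 60).
#' @param genes_per_set Members per set (default 8).
#' @param overlap_fraction Fraction of each set drawn from the shared
#'   universe (default 0.1; 0 gives pairwise-disjoint sets).
#' @param n_samples,k,delta,sigma,seed The stated world (defaults 2000
#'   cells, 7 classes, shift 2, noise 1).
#' @param relevant_per_class Planted relevant sets per class (default 2).
#' @param label_in_set_prob Probability a set contains its own labeling TF
#'   (default 0.15).
#' @return List with `expression` (cells x genes matrix), `sets` (a
#'   [gene_set_collection()]), `labels` (integer), `class_names`, and
#'   `truth` (k x n_sets logical matrix of planted relevance).
#' @export
generate_expression_with_sets <- function(n_genes = 500L, n_sets = 60L,
                                          genes_per_set = 8L,
                                          overlap_fraction = 0.1,
                                          n_samples = 2000L, k = 7L,
                                          delta = 2, sigma = 1, seed = 1L,
                                          relevant_per_class = 2L,
                                          label_in_set_prob = 0.15) {
  own_count <- ceiling(genes_per_set * (1 - overlap_fraction))
  if (own_count * n_sets > n_genes)
    stop("infeasible overlap: need ", own_count * n_sets,
         " private genes but universe has ", n_genes)
  if (relevant_per_class * k > n_sets)
    stop("relevant_per_class * k exceeds n_sets")
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  pool <- sample(genes)                       # shuffled private-gene pool
  shared_count <- genes_per_set - own_count
  sets <- vector("list", n_sets)
  labels_tf <- sample(genes, n_sets)          # distinct labeling symbols
  for (s in seq_len(n_sets)) {
    own <- pool[((s - 1L) * own_count + 1L):(s * own_count)]
    members <- own
    if (shared_count > 0L)
      members <- unique(c(own, sample(setdiff(genes, own), shared_count)))
    lab <- labels_tf[s]
    if (stats::runif(1) < label_in_set_prob) members <- unique(c(members, lab))
    else members <- setdiff(members, lab)
    sets[[s]] <- list(label = lab, category = "regulon", genes = members)
  }
  collection <- gene_set_collection(sets)
  labels <- balanced_labels(n_samples, k)
  class_names <- paste0("class_", seq_len(k))
  relevance <- matrix(FALSE, k, n_sets,
                      dimnames = list(class = class_names,
                                      set = labels_tf))
  expr <- matrix(stats::rnorm(n_samples * n_genes, 0, sigma), n_samples,
                 n_genes, dimnames = list(sprintf("cell_%05d",
                                                  seq_len(n_samples)),
                                          genes))
  set_order <- sample.int(n_sets)             # which sets carry signal
  for (t in seq_len(k)) {
    rel <- set_order[((t - 1L) * relevant_per_class + 1L):
                       (t * relevant_per_class)]
    relevance[t, rel] <- TRUE
    if (delta > 0) {
      gs <- unique(unlist(lapply(sets[rel], `[[`, "genes")))
      gi <- match(intersect(gs, genes), genes)
      expr[labels == t, gi] <- expr[labels == t, gi] + delta
    }
  }
  if (delta == 0) relevance[] <- FALSE
  expr <- pmax(expr, 0)
  list(expression = expr, sets = collection, labels = labels,
       class_names = class_names,
       truth = structure(list(informative = relevance, shift = delta),
                         class = "synth_truth"))
}

#' Write a gene-set collection as a GMT file
#'
#' @param sets A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(sets$sets, function(s)
    paste(c(s$label, s$category, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic dataset directory ready for the CLI
#'
#' Emits one TSV per source, a JSON manifest (source name, kind, features,
#' file), `labels.tsv`, and `ground_truth.json`.
#'
#' @param generated The list returned by [generate_modular()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_modular_dataset <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generated$dataset
  manifest <- list(sources = list())
  for (i in seq_along(ds$sources)) {
    src <- ds$sources[[i]]
    fn <- paste0("source_", src$name, ".tsv")
    utils::write.table(ds$blocks[[i]], file.path(dir, fn), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$sources[[i]] <- list(name = src$name, kind = src$kind,
                                  features = src$features, file = fn)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  utils::write.table(
    data.frame(sample = seq_len(n_samples(ds)),
               label = ds$class_names[ds$labels]),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(informative = generated$truth$informative,
         shift = generated$truth$shift,
         classes = ds$class_names),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
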