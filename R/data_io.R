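#' Read a tab-separated expression matrix
#'
#' Reads steady-state expression data in the layout used by the DREAM
#' network-inference challenges: a mandatory header row of unique gene
#' identifiers followed by one tab-separated row of numeric values per
#' sample.
#'
#' @param path Path to a tab-separated text file. The first line must be a
#'   header of gene identifiers; a first line that parses entirely as
#'   numbers is rejected rather than silently auto-named.
#' @return A numeric matrix with samples in rows and genes in columns;
#'   column names are the gene identifiers, in file order.
#' @examples
#' f <- tempfile()
#' writeLines(c("G1\tG2", "0.1\t0.2", "1.0\t1.1"), f)
#' read_expression(f)
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  while (length(lines) > 0 && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) < 1) stopf("expression file is empty: %s", path)
  gene_ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (any(!nzchar(gene_ids))) {
    stopf("empty gene identifier in header of %s", path)
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0) {
    stopf("duplicate gene identifier in header: %s", dup[1])
  }
  if (!anyNA(suppressWarnings(as.numeric(gene_ids)))) {
    stopf("header row of %s parses entirely as numbers; a gene identifier header is required", path)
  }
  g <- length(gene_ids)
  body <- lines[-1]
  if (length(body) == 0) stopf("expression file %s has a header but no samples", path)
  cells <- strsplit(body, "\t", fixed = TRUE)
  lens <- lengths(cells)
  if (any(lens != g)) {
    bad <- which(lens != g)[1]
    stopf("ragged row %d in %s: %d fields, expected %d", bad, path, lens[bad], g)
  }
  values <- suppressWarnings(vapply(cells, as.numeric, numeric(g)))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stopf("non-numeric cell at row %d, column %d ('%s') in %s",
          idx[2], idx[1], cells[[idx[2]]][idx[1]], path)
  }
  mat <- if (g == 1) matrix(values, ncol = 1) else t(values)
  if (any(!is.finite(mat))) {
    idx <- which(!is.finite(mat), arr.ind = TRUE)[1, ]
    stopf("non-finite expression value at row %d, column %d in %s",
          idx[1], idx[2], path)
  }
  colnames(mat) <- gene_ids
  mat
}

#' Read a transcription-factor list
#'
#' One gene identifier per line; blank lines are ignored, duplicates are
#' collapsed to the first occurrence with a warning.
#'
#' @param path Path to the text file.
#' @return Character vector of regulator identifiers in order of first
#'   occurrence.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) stopf("TF list file not found: %s", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0) stopf("TF list %s contains no candidate regulators", path)
  if (anyDuplicated(ids)) {
    warning(sprintf("duplicate identifiers in TF list %s collapsed to first occurrence", path),
            call. = FALSE)
    ids <- ids[!duplicated(ids)]
  }
  ids
}

#' Read a gold-standard edge list
#'
#' Three tab-separated columns: regulator, target, label (0 or 1).
#' Self-regulatory interactions are outside the prediction universe, so a
#' self-loop labeled 1 is an error; pairs absent from the file are treated
#' as negatives at evaluation time.
#'
#' @param path Path to the gold-standard file.
#' @return A `data.frame` with character columns `regulator`, `target` and
#'   integer column `label`.
#' @export
read_gold_standard <- function(path) {
  if (!file.exists(path)) stopf("gold standard file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(regulator = character(), target = character(),
                      label = integer(), stringsAsFactors = FALSE))
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(cells)
  if (any(lens != 3)) {
    bad <- which(lens != 3)[1]
    stopf("gold standard line %d has %d fields, expected 3 (regulator, target, label)",
          bad, lens[bad])
  }
  reg <- vapply(cells, `[[`, character(1), 1)
  tgt <- vapply(cells, `[[`, character(1), 2)
  lab_chr <- vapply(cells, `[[`, character(1), 3)
  if (!all(lab_chr %in% c("0", "1"))) {
    bad <- which(!lab_chr %in% c("0", "1"))[1]
    stopf("gold standard line %d: label '%s' is not 0 or 1", bad, lab_chr[bad])
  }
  lab <- as.integer(lab_chr)
  self_pos <- reg == tgt & lab == 1L
  if (any(self_pos)) {
    stopf("gold standard line %d labels the self-loop %s -> %s as positive; self-regulatory interactions are ignored",
          which(self_pos)[1], reg[which(self_pos)[1]], tgt[which(self_pos)[1]])
  }
  key <- paste(reg, tgt, sep = "\t")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    if (any(tapply(lab, key, function(x) length(unique(x))) > 1)) {
      stopf("gold standard contains a pair with conflicting labels")
    }
    reg <- reg[first]; tgt <- tgt[first]; lab <- lab[first]
  }
  data.frame(regulator = reg, target = tgt, label = lab,
             stringsAsFactors = FALSE)
}

validate_ranked_edges <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("regulator", "target", "score") %in% names(edges)))
  if (any(!is.finite(edges$score))) stopf("ranked edge list contains non-finite scores")
  if (is.unsorted(-edges$score)) {
    stopf("ranked edge list scores must be non-increasing")
  }
  if (any(edges$regulator == edges$target)) {
    stopf("ranked edge list contains a self-loop")
  }
  key <- paste(edges$regulator, edges$target, sep = "\t")
  if (anyDuplicated(key)) {
    stopf("ranked edge list contains a duplicated (regulator, target) pair")
  }
  invisible(edges)
}

#' Write a ranked edge list
#'
#' Serializes the ranking as `regulator<TAB>target<TAB>score`, one edge per
#' line in list order. Scores are printed with 17 significant digits so the
#' ranking round-trips exactly through [read_ranked_edges()].
#'
#' @param edges A `data.frame` with columns `regulator`, `target`, `score`,
#'   sorted by non-increasing score, with no duplicate pairs and no
#'   self-loops.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ranked_edges <- function(edges, path) {
  validate_ranked_edges(edges)
  lines <- sprintf("%s\t%s\t%.17g", edges$regulator, edges$target, edges$score)
  writeLines(lines, path)
  invisible(path)
}

#' Read a ranked edge list
#'
#' Inverse of [write_ranked_edges()].
#'
#' @param path Path to a 3-column tab-separated prediction file.
#' @return A `data.frame` with columns `regulator`, `target`, `score`.
#' @export
read_ranked_edges <- function(path) {
  if (!file.exists(path)) stopf("prediction file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(regulator = character(), target = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(cells) != 3)) {
    stopf("prediction file %s is not 3-column tab-separated", path)
  }
  score <- suppressWarnings(as.numeric(vapply(cells, `[[`, character(1), 3)))
  if (anyNA(score)) stopf("non-numeric score in prediction file %s", path)
  edges <- data.frame(regulator = vapply(cells, `[[`, character(1), 1),
                      target = vapply(cells, `[[`, character(1), 2),
                      score = score, stringsAsFactors = FALSE)
  validate_ranked_edges(edges)
}
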