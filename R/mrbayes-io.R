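# Readers and writers for MrBayes-dialect output bundles, plus burn-in
# and thinning. Generic TSV traces and newline-delimited newick lists
# are accepted alongside the MrBayes dialects.

#' Read a MrBayes parameter-sample (.p) file
#'
#' Parses the tab-delimited MrBayes parameter dialect: an optional
#' bracketed ID line, a header beginning with the generation column, and
#' numeric rows. Plain TSV traces without the ID line are accepted; a
#' leading `Gen`/`Generation`/`state` column is used for generation
#' indices, otherwise row numbers are used.
#'
#' @param path Path to the file.
#' @param chain_id Chain identifier; defaults to the file name.
#' @return A [parameter_trace()].
#' @export
read_p_file <- function(path, chain_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  start <- if (grepl("^\\s*\\[", lines[[1L]])) 2L else 1L
  if (length(lines) < start) stop("no header in ", path)
  header <- strsplit(trimws(lines[[start]]), "[\t ]+")[[1L]]
  body <- lines[-seq_len(start)]
  if (!length(body)) stop("no samples in ", path)
  cells <- strsplit(trimws(body), "[\t ]+")
  nf <- lengths(cells)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[[1L]]
    stop(sprintf("ragged row at line %d of %s (%d fields, expected %d)",
                 bad + start, path, nf[[bad]], length(header)))
  }
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(cells)), ncol = length(header), byrow = TRUE))
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1L, any))[[1L]]
    stop(sprintf("non-numeric value at line %d of %s", bad + start, path))
  }
  colnames(mat) <- header
  gen_col <- if (tolower(header[[1L]]) %in% c("gen", "generation", "state", "sample"))
    1L else 0L
  generations <- if (gen_col) mat[, 1L] else seq_len(nrow(mat))
  cols <- as.data.frame(mat[, setdiff(seq_along(header), gen_col), drop = FALSE],
                        check.names = FALSE)
  parameter_trace(chain_id %||% basename(path), generations, cols)
}

#' Read a MrBayes tree-sample (.t) file
#'
#' Parses the Nexus tree-sample dialect: a `translate` block mapping
#' integer indices to taxon labels, followed by one tree statement per
#' retained sample. Files without a translate block are read with
#' literal tip labels. Newline-delimited newick files are also accepted.
#' Rooted tree statements are coerced to their unrooted representation.
#'
#' @param path Path to the file.
#' @param chain_id Chain identifier; defaults to the file name.
#' @return A [topology_trace()].
#' @export
read_t_file <- function(path, chain_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  is_nexus <- grepl("^#NEXUS", toupper(trimws(lines[[1L]])))
  if (is_nexus) {
    trees <- ape::read.nexus(path, force.multi = TRUE)
    taxa <- parse_translate_block(lines)
  } else {
    trees <- ape::read.tree(path)
    if (inherits(trees, "phylo")) trees <- c(trees)
    taxa <- NULL
  }
  if (length(trees) == 0L) stop("no trees in ", path)
  # expand ape's compressed multiPhylo tip labels before list handling
  trees <- lapply(seq_along(trees), function(i) trees[[i]])
  if (is.null(taxa)) taxa <- trees[[1L]]$tip.label
  for (i in seq_along(trees)) {
    extra <- setdiff(trees[[i]]$tip.label, taxa)
    if (length(extra))
      stop(sprintf("tree %d in %s has leaves absent from the translate table: %s",
                   i, path, paste(extra, collapse = ", ")))
  }
  topology_trace(chain_id %||% basename(path), taxa, trees)
}

# Extract the ordered label list from a Nexus translate block; NULL if
# the file has none. Errors on duplicate labels or indices.
parse_translate_block <- function(lines) {
  low <- tolower(lines)
  t0 <- grep("^\\s*translate\\b", low)
  if (!length(t0)) return(NULL)
  t0 <- t0[[1L]]
  block <- character()
  i <- t0
  repeat {
    block <- c(block, lines[[i]])
    if (grepl(";", lines[[i]])) break
    i <- i + 1L
    if (i > length(lines)) stop("unterminated translate block")
  }
  txt <- paste(block, collapse = " ")
  txt <- sub("^\\s*[Tt]ranslate", "", txt)
  txt <- sub(";.*$", "", txt)
  entries <- strsplit(txt, ",")[[1L]]
  entries <- trimws(entries)
  entries <- entries[nzchar(entries)]
  parts <- strsplit(entries, "\\s+")
  idx <- vapply(parts, `[[`, character(1L), 1L)
  lab <- vapply(parts, function(p) paste(p[-1L], collapse = " "), character(1L))
  lab <- gsub("^'|'$", "", lab)
  if (anyDuplicated(lab)) stop("duplicate taxon label in translate block")
  if (anyDuplicated(idx)) stop("duplicate index in translate block")
  lab[order(as.integer(idx))]
}

#' Read move acceptance proportions
#'
#' Accepts either a two-column name/proportion table (optionally with a
#' header) or a MrBayes-style run-log block in which acceptance lines
#' contain a proportion (possibly as a percentage) followed by a move
#' name. A row whose name contains "swap" is stored as the cold/heated
#' swap acceptance.
#'
#' @param path Path to the file.
#' @return A [move_acceptance()].
#' @export
read_acceptances <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  names_out <- character()
  props <- numeric()
  for (ln in lines) {
    m <- regmatches(ln, regexec(
      "^([A-Za-z][A-Za-z0-9_()<>,.-]*)[\t ]+([0-9.eE+-]+)\\s*%?\\s*$", ln))[[1L]]
    if (!length(m)) {
      # log dialect: "  23.4 %  (  12 %)  Move(name)"
      m2 <- regmatches(ln, regexec(
        "^([0-9.]+)\\s*%.*?([A-Za-z][A-Za-z0-9_()<>,.-]*)\\s*$", ln))[[1L]]
      if (!length(m2)) next
      nm <- m2[[3L]]
      pr <- as.numeric(m2[[2L]]) / 100
    } else {
      nm <- m[[2L]]
      pr <- as.numeric(m[[3L]])
      if (grepl("%\\s*$", ln)) pr <- pr / 100
    }
    if (is.na(pr) || pr < 0 || pr > 1)
      stop(sprintf("acceptance proportion out of [0,1] for '%s'", nm))
    names_out <- c(names_out, nm)
    props <- c(props, pr)
  }
  if (!length(props)) stop("no acceptance entries found in ", path)
  is_swap <- grepl("swap", names_out, ignore.case = TRUE)
  swap <- if (any(is_swap)) mean(props[is_swap]) else NA_real_
  move_acceptance(stats::setNames(props[!is_swap], names_out[!is_swap]), swap)
}

#' Remove burn-in from a trace
#'
#' Discards the first `ceiling(fraction * n)` samples of a parameter or
#' topology trace; the remaining sample order is preserved. The ceiling
#' convention removes at least the requested fraction.
#'
#' @param trace A [parameter_trace()] or [topology_trace()].
#' @param fraction Burn-in fraction in \eqn{[0, 1)}; the conventional
#'   fixed value for this pipeline is 0.25.
#' @return A trace of the same class.
#' @export
apply_burnin <- function(trace, fraction = 0.25) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 1)
    stop("burn-in fraction must lie in [0, 1)")
  n <- trace$n_samples
  drop <- ceiling(fraction * n)
  if (drop >= n) stop("burn-in removes every sample")
  subset_trace(trace, (drop + 1L):n)
}

#' Thin a trace to a fixed number of samples
#'
#' Retains an evenly spaced subsample of exactly `keep` samples, always
#' including the last sample: indices `floor(k * n / keep)` for
#' `k = 1..keep`.
#'
#' @param trace A [parameter_trace()] or [topology_trace()].
#' @param keep Number of samples to retain (`1 <= keep <= n`).
#' @return A trace of the same class with `keep` samples.
#' @export
thin_trace <- function(trace, keep) {
  if (!is_count(keep) || keep <= 0) stop("keep must be a positive count")
  n <- trace$n_samples
  if (keep > n) stop("keep exceeds the number of samples")
  idx <- floor(seq_len(keep) * (n / keep))
  subset_trace(trace, idx)
}

subset_trace <- function(trace, idx) {
  if (inherits(trace, "parameter_trace")) {
    parameter_trace(trace$chain_id, trace$generations[idx],
                    trace$columns[idx, , drop = FALSE])
  } else if (inherits(trace, "topology_trace")) {
    trees <- trace$trees[idx]
    tix <- attr(trace$trees, "phyloconv_index")
    if (!is.null(tix)) {
      attr(trees, "phyloconv_index") <-
        list(ids = tix$ids[idx], unique_trees = tix$unique_trees)
    }
    topology_trace(trace$chain_id, trace$taxa, trees)
  } else stop("unsupported trace type")
}

#' Write a run set as a MrBayes-style bundle
#'
#' Emits one `.p` and one `.t` file per chain (the `.t` files carry a
#' translate block) plus a move-acceptance table, in the dialects read
#' by [read_p_file()], [read_t_file()] and [read_acceptances()]. Values
#' are printed with enough digits for a lossless round-trip.
#'
#' @param runset A [run_set()].
#' @param dir Output directory (created if needed).
#' @param digits Significant digits for printed real values.
#' @return Invisibly, the character vector of files written.
#' @export
write_mrbayes_bundle <- function(runset, dir, digits = 17L) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create directory ", dir)
  }
  id <- runset$analysis_id
  files <- character()
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  for (k in seq_along(runset$param_traces)) {
    pt <- runset$param_traces[[k]]
    pfile <- file.path(dir, sprintf("%s.run%d.p", id, k))
    hdr <- c("Gen", names(pt$columns))
    rows <- cbind(fmt(pt$generations),
                  do.call(cbind, lapply(pt$columns, fmt)))
    writeLines(c(sprintf("[ID: %s run %d]", id, k),
                 paste(hdr, collapse = "\t"),
                 apply(rows, 1L, paste, collapse = "\t")),
               pfile)
    files <- c(files, pfile)

    tt <- runset$topo_traces[[k]]
    tfile <- file.path(dir, sprintf("%s.run%d.t", id, k))
    taxa <- tt$taxa
    trans <- sprintf("\t\t%d %s%s", seq_along(taxa), taxa,
                     c(rep(",", length(taxa) - 1L), ";"))
    tree_lines <- vapply(seq_along(tt$trees), function(i) {
      tr <- tt$trees[[i]]
      tr$tip.label <- as.character(match(tr$tip.label, taxa))
      sprintf("\ttree gen.%s = [&U] %s",
              fmt(tt_generation(runset, k, i)),
              ape::write.tree(tr, digits = digits))
    }, character(1L))
    writeLines(c("#NEXUS",
                 sprintf("[ID: %s run %d]", id, k),
                 "begin trees;",
                 "\ttranslate", trans, tree_lines, "end;"),
               tfile)
    files <- c(files, tfile)
  }
  if (!is.null(runset$acceptance)) {
    afile <- file.path(dir, sprintf("%s.acceptances.tsv", id))
    acc <- runset$acceptance
    ln <- sprintf("%s\t%s", names(acc$moves), fmt(acc$moves))
    if (!is.na(acc$swap_acceptance))
      ln <- c(ln, sprintf("Swap(1<>2)\t%s", fmt(acc$swap_acceptance)))
    writeLines(ln, afile)
    files <- c(files, afile)
  }
  invisible(files)
}

tt_generation <- function(runset, chain, i) {
  runset$param_traces[[chain]]$generations[[i]]
}

#' Read a MrBayes-style bundle directory as a run set
#'
#' Pairs `<id>.run<k>.p` with `<id>.run<k>.t` files under `dir` and
#' reads an acceptance table if one is present.
#'
#' @param dir Directory containing the bundle.
#' @param analysis_id Analysis identifier; default the directory name.
#' @param n_characters Optional alignment length to attach.
#' @return A [run_set()].
#' @export
read_mrbayes_bundle <- function(dir, analysis_id = NULL, n_characters = NULL) {
  pfiles <- sort(list.files(dir, pattern = "\\.p$", full.names = TRUE))
  if (!length(pfiles)) stop("no .p files in ", dir)
  tfiles <- sub("\\.p$", ".t", pfiles)
  if (!all(file.exists(tfiles))) stop("missing .t file for some .p file in ", dir)
  chains <- sub("\\.p$", "", basename(pfiles))
  pts <- mapply(read_p_file, pfiles, chains, SIMPLIFY = FALSE)
  tts <- mapply(read_t_file, tfiles, chains, SIMPLIFY = FALSE)
  afile <- list.files(dir, pattern = "acceptances", full.names = TRUE)
  acc <- if (length(afile)) read_acceptances(afile[[1L]]) else NULL
  run_set(analysis_id %||% basename(normalizePath(dir)),
          pts, tts, n_characters = n_characters, acceptance = acc)
}
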