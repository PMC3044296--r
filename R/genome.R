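#' Construct a genome of signed gene orders
#'
#' A genome is a set of linear chromosomes, each an ordered run of signed
#' integer gene identifiers over a shared universe `1..n`. The sign encodes
#' the strand (reading orientation) of the gene. Every gene of the universe
#' must appear exactly once, in exactly one orientation, across the
#' chromosomes.
#'
#' @param chromosomes a list of integer vectors (or a single integer vector,
#'   taken as a one-chromosome genome). Signed, non-zero, duplicate-free.
#' @param name optional character label.
#' @param n size of the gene universe; defaults to the number of genes
#'   present. Supplying `n` larger than the genes present is an error.
#' @return an object of class `"genome"`: a list with elements
#'   `chromosomes`, `name` and `n`.
#' @examples
#' g <- genome(list(c(1L, -3L, 2L), 4L), name = "A")
#' g
#' @export
genome <- function(chromosomes, name = NULL, n = NULL) {
  if (is.numeric(chromosomes)) chromosomes <- list(chromosomes)
  if (!is.list(chromosomes) || length(chromosomes) == 0L)
    stop_pg("pg_invalid_genome", "a genome needs at least one chromosome")
  chromosomes <- lapply(chromosomes, function(ch) {
    if (length(ch) == 0L)
      stop_pg("pg_invalid_genome", "chromosomes must be non-empty")
    if (!is.numeric(ch) || any(ch != as.integer(ch)))
      stop_pg("pg_bad_gene_token", "gene identifiers must be integers")
    as.integer(ch)
  })
  genes <- abs(unlist(chromosomes))
  if (any(genes == 0L))
    stop_pg("pg_bad_gene_token", "gene identifier 0 is not allowed")
  if (anyDuplicated(genes))
    stop_pg("pg_duplicate_gene",
            sprintf("duplicated gene(s): %s",
                    paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  if (is.null(n)) n <- max(genes)
  n <- as.integer(n)
  if (length(setdiff(seq_len(n), genes)) > 0L)
    stop_pg("pg_missing_gene",
            sprintf("gene(s) missing from genome: %s",
                    paste(setdiff(seq_len(n), genes), collapse = ", ")))
  if (any(genes > n))
    stop_pg("pg_invalid_genome", "gene identifier exceeds the stated universe")
  structure(list(chromosomes = chromosomes, name = name, n = n),
            class = "genome")
}

stop_pg <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "pg_error", "error")))
}

#' @export
print.genome <- function(x, ...) {
  nm <- if (is.null(x$name)) "<unnamed>" else x$name
  cat(sprintf("Genome %s: %d genes on %d chromosome(s)\n",
              nm, x$n, length(x$chromosomes)))
  for (ch in x$chromosomes)
    cat(" ", paste(ch, collapse = " "), "$\n")
  invisible(x)
}

#' Canonical form of a genome
#'
#' Flips each chromosome (reverse and negate) so that the absolute
#' identifier of its first gene is smaller than that of its last (a
#' single-gene chromosome is flipped to positive sign), then sorts
#' chromosomes by the absolute identifier of their first gene. Two genomes
#' are equivalent exactly when their canonical forms are identical, which
#' makes equality invariant under chromosome reordering and
#' whole-chromosome reversal-with-negation.
#'
#' @param g a [genome].
#' @return a `genome` in canonical form (name preserved).
#' @export
canonical_genome <- function(g) {
  stopifnot(inherits(g, "genome"))
  chroms <- lapply(g$chromosomes, function(ch) {
    m <- length(ch)
    if (m == 1L) {
      if (ch < 0L) -ch else ch
    } else if (abs(ch[1L]) > abs(ch[m])) {
      -rev(ch)
    } else ch
  })
  ord <- order(vapply(chroms, function(ch) abs(ch[1L]), integer(1)))
  structure(list(chromosomes = chroms[ord], name = g$name, n = g$n),
            class = "genome")
}

#' Test two genomes for equivalence
#'
#' Equivalence ignores chromosome order and whole-chromosome orientation
#' (a chromosome read backwards with all signs negated is the same
#' chromosome).
#'
#' @param a,b [genome] objects.
#' @return `TRUE` or `FALSE`.
#' @export
genome_equal <- function(a, b) {
  if (a$n != b$n) return(FALSE)
  ca <- canonical_genome(a)$chromosomes
  cb <- canonical_genome(b)$chromosomes
  identical(ca, cb)
}

n_genes <- function(g) g$n
n_chromosomes <- function(g) length(g$chromosomes)

#' Read genomes from a GRIMM-style gene-order file
#'
#' The dialect: a line starting with `>` opens a genome and carries its
#' name; subsequent whitespace-separated signed integers are genes; a `$`
#' token ends a chromosome; lines starting with `#` are comments. All
#' genomes in a file must share the same gene universe `1..n`, inferred
#' from the union of absolute identifiers.
#'
#' @param path file path.
#' @return a named list of [genome] objects (possibly empty).
#' @export
read_genomes <- function(path) {
  if (!file.exists(path))
    stop_pg("pg_io_error", sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  genomes <- list()
  cur_name <- NULL
  cur_chroms <- list()
  cur_genes <- integer(0)
  flush_chrom <- function() {
    if (length(cur_genes) > 0L) {
      cur_chroms[[length(cur_chroms) + 1L]] <<- cur_genes
      cur_genes <<- integer(0)
    }
  }
  flush_genome <- function() {
    if (is.null(cur_name)) return()
    flush_chrom()
    if (length(cur_chroms) == 0L)
      stop_pg("pg_invalid_genome",
              sprintf("genome '%s' has no chromosomes", cur_name))
    genomes[[cur_name]] <<- cur_chroms
    cur_chroms <<- list()
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    if (startsWith(ln, ">")) {
      flush_genome()
      cur_name <- trimws(substring(ln, 2L))
      if (cur_name == "")
        stop_pg("pg_io_error", "genome header '>' without a name")
      next
    }
    if (is.null(cur_name))
      stop_pg("pg_io_error", "gene data before any '>' header")
    for (tok in strsplit(ln, "\\s+")[[1L]]) {
      if (tok == "$") {
        flush_chrom()
      } else {
        v <- suppressWarnings(as.integer(tok))
        if (is.na(v) || as.character(v) != tok)
          stop_pg("pg_bad_gene_token", sprintf("bad gene token '%s'", tok))
        if (v == 0L)
          stop_pg("pg_bad_gene_token", "gene identifier 0 is not allowed")
        cur_genes <- c(cur_genes, v)
      }
    }
  }
  flush_genome()
  if (length(genomes) == 0L) return(list())
  universe <- max(vapply(genomes, function(ch) max(abs(unlist(ch))), integer(1)))
  out <- lapply(names(genomes), function(nm) {
    g <- tryCatch(
      genome(genomes[[nm]], name = nm, n = universe),
      pg_missing_gene = function(e)
        stop_pg("pg_unequal_content",
                sprintf("genome '%s': %s (genomes must share one gene universe)",
                        nm, conditionMessage(e))))
    g
  })
  names(out) <- names(genomes)
  out
}

#' Write genomes to a GRIMM-style gene-order file
#'
#' Inverse of [read_genomes()]: reading the written file recovers the same
#' genomes up to chromosome order and whole-chromosome flips.
#'
#' @param genomes a list of [genome] objects (names taken from the genomes,
#'   falling back to list names or `G1`, `G2`, ...).
#' @param path output file path.
#' @param header optional character vector written as leading `#` comments.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(genomes, path, header = NULL) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  lines <- character(0)
  if (!is.null(header)) lines <- paste("#", header)
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    stopifnot(inherits(g, "genome"))
    nm <- g$name
    if (is.null(nm) || !nzchar(nm)) nm <- names(genomes)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("G", i)
    lines <- c(lines, paste0(">", nm),
               vapply(g$chromosomes,
                      function(ch) paste(c(ch, "$"), collapse = " "),
                      character(1)))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_pg("pg_io_error", sprintf("cannot write to '%s'", path))
  invisible(path)
}
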