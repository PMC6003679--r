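#' Read loci from a `.loci` text file or per-locus FASTA
#'
#' Two plain-text dialects are supported. `"loci"` is the assembler-style
#' block format: each locus is a run of `sampleid<whitespace>sequence`
#' lines closed by a line starting with `//` (locus ids are taken from a
#' trailing `|<id>|` on the separator when present, otherwise numbered in
#' file order). `"fasta"` is concatenated per-locus FASTA with headers of
#' the form `>locus<id>|<sample>`.
#'
#' @param path input file path.
#' @param dialect `"loci"` or `"fasta"`.
#' @param samples optional sample registry (character vector or data
#'   frame) to cross-check sample ids against.
#' @return a [locus_set()].
#' @export
read_loci <- function(path, dialect = c("loci", "fasta"), samples = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  ls <- switch(dialect,
               loci = .parse_loci_blocks(lines),
               fasta = .parse_locus_fasta(lines))
  if (!is.null(samples)) {
    ls <- locus_set(ls$loci, samples = samples, provenance = ls$provenance)
  }
  ls
}

.parse_loci_blocks <- function(lines) {
  loci <- list()
  cur <- character()
  ordinal <- 0L
  for (ln in lines) {
    if (startsWith(ln, "//")) {
      ordinal <- ordinal + 1L
      if (length(cur) == 0L)
        stop("malformed block: locus ", ordinal, " is empty")
      id <- ordinal
      m <- regmatches(ln, regexec("\\|([0-9]+)\\|", ln))[[1]]
      if (length(m) == 2L) id <- as.integer(m[2])
      loci[[length(loci) + 1L]] <- tryCatch(
        rad_locus(id, cur),
        error = function(e) stop("locus ", ordinal, ": ", conditionMessage(e),
                                 call. = FALSE))
      cur <- character()
    } else if (nzchar(trimws(ln))) {
      parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(parts) != 2L)
        stop("malformed block: cannot parse line in locus ",
             length(loci) + 1L, ": '", ln, "'")
      cur[parts[1]] <- parts[2]
    }
  }
  if (length(cur) > 0L)
    stop("malformed block: trailing lines after last '//' separator")
  locus_set(loci, provenance = "read_loci(dialect = 'loci')")
}

.parse_locus_fasta <- function(lines) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("malformed FASTA: no '>' headers")
  ends <- c(hdr[-1] - 1L, length(lines))
  ids <- character(length(hdr))
  smp <- character(length(hdr))
  seqs <- character(length(hdr))
  for (i in seq_along(hdr)) {
    h <- sub("^>", "", lines[hdr[i]])
    parts <- strsplit(h, "|", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed FASTA header (expected '>locus<id>|<sample>'): ",
           lines[hdr[i]])
    ids[i] <- sub("^locus", "", parts[1])
    smp[i] <- parts[2]
    body <- lines[seq(hdr[i] + 1L, ends[i])]
    seqs[i] <- paste(trimws(body), collapse = "")
  }
  loci <- lapply(split(seq_along(ids), as.integer(ids)), function(idx) {
    s <- seqs[idx]
    names(s) <- smp[idx]
    rad_locus(as.integer(ids[idx[1]]), s)
  })
  loci <- loci[order(vapply(loci, function(l) l$locus_id, integer(1)))]
  locus_set(unname(loci), provenance = "read_loci(dialect = 'fasta')")
}

#' Write loci to a `.loci` text file or per-locus FASTA
#'
#' Emits the same dialects [read_loci()] parses, so write/read round-trips
#' are lossless (sequence content, sample ids and locus ids).
#'
#' @param ls a [locus_set()].
#' @param path output file path.
#' @param dialect `"loci"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_loci <- function(ls, path, dialect = c("loci", "fasta")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "loci") {
    w <- max(nchar(unlist(lapply(ls$loci, function(l) names(l$seqs)))), 1L)
    for (l in ls$loci) {
      nm <- formatC(names(l$seqs), width = -w)
      writeLines(paste0(nm, "  ", unname(l$seqs)), con)
      writeLines(paste0("//", strrep(" ", 2L), "|", l$locus_id, "|"), con)
    }
  } else {
    for (l in ls$loci) {
      for (s in names(l$seqs)) {
        writeLines(paste0(">locus", l$locus_id, "|", s), con)
        writeLines(unname(l$seqs[s]), con)
      }
    }
  }
  invisible(path)
}
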