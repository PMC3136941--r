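#' Construct an aligned-tag table
#'
#' Tags are held as a plain data.frame with columns \code{chrom} (character),
#' \code{start}, \code{end} (0-based half-open integers) and \code{strand}
#' ("+" or "-").  All downstream maths uses the tag's 5' end:
#' \code{start} on the forward strand, \code{end - 1} on the reverse strand.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open coordinates, \code{start < end}.
#' @param strand "+" or "-".
#' @return data.frame of class \code{c("balm_tags", "data.frame")}.
#' @export
aligned_tags <- function(chrom = character(), start = integer(),
                         end = integer(), strand = character()) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(strand))
  if (length(start) && any(start >= end)) stop("tags must satisfy start < end")
  if (length(strand) && !all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  structure(data.frame(chrom = as.character(chrom),
                       start = as.integer(start), end = as.integer(end),
                       strand = as.character(strand),
                       stringsAsFactors = FALSE),
            class = c("balm_tags", "data.frame"))
}

#' 5' positions of tags
#'
#' @param tags a tag table from \code{\link{aligned_tags}} or
#'   \code{\link{read_tags}}.
#' @return integer vector: \code{start} for forward tags, \code{end - 1} for
#'   reverse tags (0-based).
#' @export
tag_pos5 <- function(tags) {
  ifelse(tags$strand == "+", tags$start, tags$end - 1L)
}

#' Describe a genome assembly
#'
#' @param chrom_lengths named integer vector: chromosome name -> length (bp).
#' @param exclude optional data.frame (chrom, start, end) of 0-based
#'   half-open intervals (pericentromeric / repetitive regions) to exclude.
#' @return list of class \code{genome_assembly} with \code{chrom_lengths},
#'   \code{exclude} and total \code{genome_size}.
#' @export
genome_assembly <- function(chrom_lengths, exclude = NULL) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0))
  if (!is.null(exclude)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(exclude)))
    bad <- !(exclude$chrom %in% names(chrom_lengths)) |
      exclude$start < 0 |
      exclude$end > chrom_lengths[exclude$chrom] |
      exclude$start >= exclude$end
    if (any(bad)) stop("exclusion intervals outside assembly bounds")
  }
  structure(list(chrom_lengths = chrom_lengths,
                 exclude = exclude,
                 genome_size = sum(as.numeric(chrom_lengths))),
            class = "genome_assembly")
}

#' Read a genome assembly from a two-column table
#'
#' Plain text, tab- or space-separated: chromosome name, length in bp.
#'
#' @param path file path.
#' @param exclude_bed optional BED file of exclusion intervals.
#' @return a \code{\link{genome_assembly}}.
#' @export
read_genome_table <- function(path, exclude_bed = NULL) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("genome table needs two columns: chrom, length")
  lens <- as.integer(tab[[2]])
  names(lens) <- as.character(tab[[1]])
  excl <- NULL
  if (!is.null(exclude_bed)) {
    b <- utils::read.table(exclude_bed, header = FALSE,
                           stringsAsFactors = FALSE)
    excl <- data.frame(chrom = as.character(b[[1]]),
                       start = as.integer(b[[2]]), end = as.integer(b[[3]]),
                       stringsAsFactors = FALSE)
  }
  genome_assembly(lens, excl)
}

.parse_strand <- function(s, path, lineno) {
  out <- rep(NA_character_, length(s))
  out[s %in% c("+", "F", "f", "0")] <- "+"
  out[s %in% c("-", "R", "r", "16")] <- "-"
  if (anyNA(out)) {
    stop(sprintf("%s: malformed strand '%s' at line %d", path,
                 s[which(is.na(out))[1]], lineno[which(is.na(out))[1]]))
  }
  out
}

.check_int <- function(v, what, path, lineno) {
  x <- suppressWarnings(as.integer(v))
  if (anyNA(x)) {
    i <- which(is.na(x))[1]
    stop(sprintf("%s: malformed %s '%s' at line %d", path, what, v[i],
                 lineno[i]))
  }
  x
}

.split_fields <- function(lines) {
  strsplit(lines, "\t", fixed = TRUE)
}

.cigar_reflen <- function(cigar, seq) {
  n <- length(cigar)
  out <- integer(n)
  use_seq <- cigar == "*"
  out[use_seq] <- nchar(seq[use_seq])
  if (any(!use_seq)) {
    lens <- regmatches(cigar[!use_seq],
                       gregexpr("[0-9]+[MIDNSHP=X]", cigar[!use_seq]))
    out[!use_seq] <- vapply(lens, function(ops) {
      op <- substring(ops, nchar(ops))
      len <- as.integer(substring(ops, 1, nchar(ops) - 1))
      sum(len[op %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
  }
  out
}

#' Read aligned tags in any supported dialect
#'
#' Supported formats and their coordinate conventions:
#' \describe{
#'   \item{BED}{0-based half-open; columns chrom, start, end, (name, score,)
#'     strand.}
#'   \item{GFF}{1-based inclusive; columns seqname, source, feature, start,
#'     end, score, strand.}
#'   \item{SAM}{text SAM; header lines skipped, unmapped records (FLAG bit
#'     0x4) skipped, strand from FLAG bit 0x10, reference span from CIGAR.}
#'   \item{ELAND}{tab-separated \code{s_*_eland_result}-style: id, sequence,
#'     match code, then chromosome (col 7), 1-based leftmost position
#'     (col 8), strand F/R (col 9).  Only uniquely mapped records
#'     (U0/U1/U2) are kept.}
#'   \item{EXTENDED_ELAND}{\code{s_*_export}-style: sequence col 9,
#'     chromosome col 11, 1-based position col 13, strand col 14; records
#'     whose chromosome field is not a sequence name (NM, QC, ...) are
#'     skipped.}
#'   \item{BOWTIE}{bowtie default output: name, strand, chromosome, 0-based
#'     leftmost offset, sequence.}
#'   \item{CUSTOM}{any columnar text; \code{custom_columns} gives the
#'     0-based indices of chromosome, start, end, strand, read as 0-based
#'     half-open.}
#' }
#' Parsing is strict: a malformed line is a fatal error reporting the line
#' number, because silently dropped records corrupt depth statistics.
#'
#' @param path file path.
#' @param format one of "BED", "ELAND", "EXTENDED_ELAND", "GFF", "SAM",
#'   "BOWTIE", "CUSTOM".
#' @param custom_columns for CUSTOM: integer vector of four 0-based column
#'   indices (chrom, start, end, strand), e.g. \code{c(0, 1, 2, 5)}.
#' @return a tag table (see \code{\link{aligned_tags}}), coordinates
#'   normalized to 0-based half-open.
#' @export
read_tags <- function(path, format = "BED", custom_columns = NULL) {
  format <- toupper(format)
  known <- c("BED", "ELAND", "EXTENDED_ELAND", "GFF", "SAM", "BOWTIE",
             "CUSTOM")
  if (!format %in% known)
    stop("unknown tag format '", format, "'; supported: ",
         paste(known, collapse = ", "))
  if (!file.exists(path)) stop("tag file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  if (format == "SAM") keep <- keep & !startsWith(lines, "@")
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) return(aligned_tags())

  if (format %in% c("BED", "GFF", "CUSTOM")) {
    f <- if (format == "BED") .split_fields(lines)
         else if (format == "GFF") .split_fields(lines)
         else strsplit(lines, "[ \t]+")
    nf <- lengths(f)
    need <- switch(format, BED = 6L, GFF = 7L,
                   CUSTOM = max(custom_columns) + 1L)
    if (format == "CUSTOM" &&
        (is.null(custom_columns) || length(custom_columns) != 4))
      stop("CUSTOM format requires custom_columns = 4 column indices")
    if (any(nf < need)) {
      i <- which(nf < need)[1]
      stop(sprintf("%s: line %d has %d fields, need >= %d", path,
                   lineno[i], nf[i], need))
    }
    get <- function(j) vapply(f, `[[`, character(1), j)
    if (format == "BED") {
      chrom <- get(1)
      start <- .check_int(get(2), "start", path, lineno)
      end <- .check_int(get(3), "end", path, lineno)
      strand <- .parse_strand(get(6), path, lineno)
    } else if (format == "GFF") {
      chrom <- get(1)
      start <- .check_int(get(4), "start", path, lineno) - 1L  # 1-based incl.
      end <- .check_int(get(5), "end", path, lineno)
      strand <- .parse_strand(get(7), path, lineno)
    } else {
      cc <- custom_columns + 1L
      chrom <- get(cc[1])
      start <- .check_int(get(cc[2]), "start", path, lineno)
      end <- .check_int(get(cc[3]), "end", path, lineno)
      strand <- .parse_strand(get(cc[4]), path, lineno)
    }
  } else if (format == "SAM") {
    f <- .split_fields(lines)
    nf <- lengths(f)
    if (any(nf < 11)) {
      i <- which(nf < 11)[1]
      stop(sprintf("%s: SAM line %d has %d fields, need >= 11", path,
                   lineno[i], nf[i]))
    }
    flag <- .check_int(vapply(f, `[[`, character(1), 2), "FLAG", path, lineno)
    mapped <- bitwAnd(flag, 4L) == 0L
    f <- f[mapped]; lineno <- lineno[mapped]; flag <- flag[mapped]
    if (!length(f)) return(aligned_tags())
    chrom <- vapply(f, `[[`, character(1), 3)
    pos <- .check_int(vapply(f, `[[`, character(1), 4), "POS", path, lineno)
    start <- pos - 1L
    reflen <- .cigar_reflen(vapply(f, `[[`, character(1), 6),
                            vapply(f, `[[`, character(1), 10))
    if (any(reflen <= 0)) {
      i <- which(reflen <= 0)[1]
      stop(sprintf("%s: SAM line %d: cannot determine alignment length",
                   path, lineno[i]))
    }
    end <- start + reflen
    strand <- ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")
  } else if (format == "ELAND") {
    f <- .split_fields(lines)
    code <- vapply(f, function(x) if (length(x) >= 3) x[[3]] else "", character(1))
    uniq <- code %in% c("U0", "U1", "U2")
    f <- f[uniq]; lineno <- lineno[uniq]
    if (!length(f)) return(aligned_tags())
    nf <- lengths(f)
    if (any(nf < 9)) {
      i <- which(nf < 9)[1]
      stop(sprintf("%s: ELAND line %d has %d fields, need >= 9", path,
                   lineno[i], nf[i]))
    }
    chrom <- vapply(f, `[[`, character(1), 7)
    pos <- .check_int(vapply(f, `[[`, character(1), 8), "position", path,
                      lineno)
    taglen <- nchar(vapply(f, `[[`, character(1), 2))
    start <- pos - 1L                       # 1-based leftmost
    end <- start + taglen
    strand <- .parse_strand(vapply(f, `[[`, character(1), 9), path, lineno)
  } else if (format == "EXTENDED_ELAND") {
    f <- .split_fields(lines)
    nf <- lengths(f)
    if (any(nf < 14)) {
      i <- which(nf < 14)[1]
      stop(sprintf("%s: export line %d has %d fields, need >= 14", path,
                   lineno[i], nf[i]))
    }
    chrom <- vapply(f, `[[`, character(1), 11)
    mapped <- !chrom %in% c("NM", "QC", "RM", "") &
      !grepl("^[0-9]+:[0-9]+:[0-9]+$", chrom)
    f <- f[mapped]; lineno <- lineno[mapped]; chrom <- chrom[mapped]
    if (!length(f)) return(aligned_tags())
    pos <- .check_int(vapply(f, `[[`, character(1), 13), "position", path,
                      lineno)
    taglen <- nchar(vapply(f, `[[`, character(1), 9))
    start <- pos - 1L
    end <- start + taglen
    strand <- .parse_strand(vapply(f, `[[`, character(1), 14), path, lineno)
  } else { # BOWTIE
    f <- .split_fields(lines)
    nf <- lengths(f)
    if (any(nf < 5)) {
      i <- which(nf < 5)[1]
      stop(sprintf("%s: bowtie line %d has %d fields, need >= 5", path,
                   lineno[i], nf[i]))
    }
    strand <- .parse_strand(vapply(f, `[[`, character(1), 2), path, lineno)
    chrom <- vapply(f, `[[`, character(1), 3)
    start <- .check_int(vapply(f, `[[`, character(1), 4), "offset", path,
                        lineno)                                  # 0-based
    end <- start + nchar(vapply(f, `[[`, character(1), 5))
  }
  if (any(start >= end)) {
    i <- which(start >= end)[1]
    stop(sprintf("%s: line %d: start >= end after normalization", path,
                 lineno[i]))
  }
  if (any(start < 0)) {
    i <- which(start < 0)[1]
    stop(sprintf("%s: line %d: negative coordinate", path, lineno[i]))
  }
  aligned_tags(chrom, start, end, strand)
}

#' Write aligned tags in any supported dialect
#'
#' The inverse of \code{\link{read_tags}}: serializes the internal 0-based
#' half-open representation into each dialect's native convention.  Sequence
#' fields that the internal representation does not carry (ELAND, SAM,
#' Bowtie) are filled with dummy bases of the correct length so coordinates
#' round-trip exactly.
#'
#' @param tags a tag table.
#' @param path output file path.
#' @param format dialect, as in \code{\link{read_tags}}.
#' @param custom_columns for CUSTOM, as in \code{\link{read_tags}}.
#' @param assembly optional \code{\link{genome_assembly}}; used to emit SAM
#'   \code{@SQ} header lines.
#' @return \code{path}, invisibly.
#' @export
write_tags <- function(tags, path, format = "BED", custom_columns = NULL,
                       assembly = NULL) {
  format <- toupper(format)
  n <- nrow(tags)
  len <- tags$end - tags$start
  dummy_seq <- vapply(len, function(l) strrep("A", l), character(1))
  lines <- switch(format,
    BED = sprintf("%s\t%d\t%d\ttag%d\t0\t%s", tags$chrom, tags$start,
                  tags$end, seq_len(n), tags$strand),
    GFF = sprintf("%s\tbalm\ttag\t%d\t%d\t.\t%s\t.", tags$chrom,
                  tags$start + 1L, tags$end, tags$strand),
    SAM = {
      flag <- ifelse(tags$strand == "-", 16L, 0L)
      body <- sprintf("tag%d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                      seq_len(n), flag, tags$chrom, tags$start + 1L, len,
                      dummy_seq)
      hdr <- "@HD\tVN:1.6\tSO:unsorted"
      if (!is.null(assembly)) {
        hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d",
                              names(assembly$chrom_lengths),
                              assembly$chrom_lengths))
      }
      c(hdr, body)
    },
    ELAND = sprintf(">tag%d\t%s\tU0\t1\t0\t0\t%s\t%d\t%s\t..", seq_len(n),
                    dummy_seq, tags$chrom, tags$start + 1L,
                    ifelse(tags$strand == "+", "F", "R")),
    EXTENDED_ELAND = sprintf(
      "M1\t1\t1\t1\t%d\t%d\t0\t1\t%s\t%s\t%s\t\t%d\t%s\t25\t.\t.\t.\t.\t.\t.\tY",
      seq_len(n), seq_len(n), dummy_seq, strrep("a", len), tags$chrom,
      tags$start + 1L, ifelse(tags$strand == "+", "F", "R")),
    BOWTIE = sprintf("tag%d\t%s\t%s\t%d\t%s\tIIII\t0\t", seq_len(n),
                     tags$strand, tags$chrom, tags$start, dummy_seq),
    CUSTOM = {
      if (is.null(custom_columns) || length(custom_columns) != 4)
        stop("CUSTOM format requires custom_columns")
      ncol <- max(custom_columns) + 1L
      m <- matrix(".", nrow = n, ncol = ncol)
      m[, custom_columns[1] + 1L] <- tags$chrom
      m[, custom_columns[2] + 1L] <- as.character(tags$start)
      m[, custom_columns[3] + 1L] <- as.character(tags$end)
      m[, custom_columns[4] + 1L] <- tags$strand
      apply(m, 1, paste, collapse = "\t")
    },
    stop("unknown tag format '", format, "'")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Filter tags against a genome assembly
#'
#' Drops tags on chromosomes absent from the assembly (with a warning),
#' removes tags overlapping the assembly's exclusion intervals, and
#' optionally collapses tags identical in (chrom, 5' position, strand) to a
#' single representative.
#'
#' @param tags a tag table.
#' @param assembly a \code{\link{genome_assembly}}.
#' @param dedup collapse presumed PCR duplicates (default FALSE).
#' @return Filtered tag table; attribute \code{"n_dropped"} counts tags
#'   removed per cause.
#' @export
filter_tags <- function(tags, assembly, dedup = FALSE) {
  stopifnot(inherits(assembly, "genome_assembly"))
  n0 <- nrow(tags)
  unknown <- !(tags$chrom %in% names(assembly$chrom_lengths))
  if (any(unknown)) {
    warning(sum(unknown), " tag(s) on chromosomes absent from assembly; dropped")
    tags <- tags[!unknown, , drop = FALSE]
  }
  n_excl <- 0L
  excl <- assembly$exclude
  if (!is.null(excl) && nrow(excl) && nrow(tags)) {
    hit <- rep(FALSE, nrow(tags))
    for (ch in unique(excl$chrom)) {
      on <- tags$chrom == ch
      if (!any(on)) next
      q <- IRanges::IRanges(start = tags$start[on] + 1L, end = tags$end[on])
      s <- excl[excl$chrom == ch, , drop = FALSE]
      sub <- IRanges::IRanges(start = s$start + 1L, end = s$end)
      hit[on] <- IRanges::overlapsAny(q, sub)
    }
    n_excl <- sum(hit)
    tags <- tags[!hit, , drop = FALSE]
  }
  n_dup <- 0L
  if (dedup && nrow(tags)) {
    key <- paste(tags$chrom, tag_pos5(tags), tags$strand)
    keep <- !duplicated(key)
    n_dup <- sum(!keep)
    tags <- tags[keep, , drop = FALSE]
  }
  rownames(tags) <- NULL
  attr(tags, "n_dropped") <- c(unknown_chrom = sum(unknown),
                               excluded = n_excl, duplicates = n_dup)
  tags
}

#' Extract CpG positions from a FASTA file
#'
#' @param fasta path to a FASTA file (or a \code{Biostrings::DNAStringSet}).
#' @return Named list, one sorted integer vector of 0-based positions of the
#'   C of each CG dinucleotide per sequence.  Case-insensitive; overlapping
#'   CGCG yields both positions.
#' @export
extract_cpg_sites <- function(fasta) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  out <- lapply(seq_along(seqs), function(i) {
    m <- Biostrings::matchPattern("CG", seqs[[i]], fixed = TRUE)
    as.integer(BiocGenerics::start(m)) - 1L
  })
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a per-position track as WIG
#'
#' @param track named list: chromosome -> either a named numeric vector
#'   (names = 0-based positions) for variable step, or a plain numeric
#'   vector starting at \code{start0} for fixed step.
#' @param path output path.
#' @param mode "variable_step" or "fixed_step".
#' @param span span (bp) for variableStep lines.
#' @param step,start0 step size and 0-based start for fixedStep mode
#'   (\code{start0} may be a named vector per chromosome).
#' @return \code{path}, invisibly.  Coordinates are written 1-based per the
#'   WIG convention; zero values are omitted in variable mode.
#' @export
write_wig <- function(track, path, mode = c("variable_step", "fixed_step"),
                      span = 1L, step = 1L, start0 = 0L) {
  mode <- match.arg(mode)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=wiggle_0", con)
  for (ch in names(track)) {
    v <- track[[ch]]
    if (mode == "variable_step") {
      pos <- suppressWarnings(as.integer(names(v)))
      if (length(v) && (is.null(names(v)) || anyNA(pos)))
        stop("variable_step track values must be named by position")
      o <- order(pos)
      pos <- pos[o]; v <- unname(v[o])
      keep <- v != 0
      writeLines(sprintf("variableStep chrom=%s span=%d", ch, span), con)
      if (any(keep))
        writeLines(sprintf("%d\t%s", pos[keep] + 1L,
                           sprintf("%.10g", v[keep])), con)
    } else {
      s0 <- if (length(start0) > 1) start0[[ch]] else start0
      writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                         ch, s0 + 1L, step, step), con)
      writeLines(sprintf("%.10g", unname(v)), con)
    }
  }
  invisible(path)
}

#' Read a WIG file written by \code{\link{write_wig}}
#'
#' Supports variableStep and fixedStep sections; positions are returned
#' 0-based.
#'
#' @param path WIG file path.
#' @return Named list per chromosome of named numeric vectors
#'   (names = 0-based positions).
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  out <- list()
  ch <- NULL; mode <- NULL; at <- NA_integer_; step <- 1L
  for (ln in lines) {
    if (startsWith(ln, "variableStep")) {
      ch <- sub('.*chrom=([^ \t]+).*', '\\1', ln)
      mode <- "v"
      if (is.null(out[[ch]])) out[[ch]] <- numeric()
    } else if (startsWith(ln, "fixedStep")) {
      ch <- sub('.*chrom=([^ \t]+).*', '\\1', ln)
      at <- as.integer(sub('.*start=([0-9]+).*', '\\1', ln)) - 1L
      step <- as.integer(sub('.*step=([0-9]+).*', '\\1', ln))
      mode <- "f"
      if (is.null(out[[ch]])) out[[ch]] <- numeric()
    } else if (!is.null(mode)) {
      if (mode == "v") {
        fld <- strsplit(ln, "[ \t]+")[[1]]
        v <- as.numeric(fld[2])
        names(v) <- as.character(as.integer(fld[1]) - 1L)
        out[[ch]] <- c(out[[ch]], v)
      } else {
        v <- as.numeric(ln)
        names(v) <- as.character(at)
        out[[ch]] <- c(out[[ch]], v)
        at <- at + step
      }
    } else stop("WIG data line before any step declaration")
  }
  out
}

#' Write regions or sites as BED
#'
#' @param df data.frame with chrom, start, end (0-based half-open) and
#'   optional name/score columns.
#' @param path output path.
#' @param names,scores optional character / numeric vectors.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(df, path, names = NULL, scores = NULL) {
  n <- nrow(df)
  if (is.null(names)) names <- paste0("region", seq_len(n))
  if (is.null(scores)) scores <- rep(0, n)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", df$chrom, as.integer(df$start),
                     as.integer(df$end), names,
                     sprintf("%.8g", scores)), path)
  invisible(path)
}
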