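#' Read a GENEPOP file of SNP genotypes
#'
#' Parses the GENEPOP dialect used for SNP data: a title line, locus names
#' (one per line or comma-separated), `Pop` separators (case-insensitive),
#' then one line per individual of the form `id , g1 g2 ...` where each
#' genotype is a fixed-width 4- or 6-character token (two 2- or 3-digit
#' allele codes). Allele codes must decode to 0 (missing), 1 or 2; anything
#' else is rejected because only biallelic SNPs are supported. A genotype
#' with any missing allele is treated as wholly missing.
#'
#' If the file contains several `Pop` blocks the individuals are
#' concatenated into one sample with a warning: the estimator is a
#' single-population method.
#'
#' @param con a file path, connection, or character vector of lines.
#' @return a [genotype_matrix()].
#' @seealso [write_genepop()]
#' @export
read_genepop <- function(con) {
  lines <- if (is.character(con) && length(con) > 1) {
    con
  } else if (is.character(con) && !file.exists(con) && grepl("\n", con)) {
    strsplit(con, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(con, warn = FALSE)
  }
  lines <- sub("[\r[:space:]]+$", "", lines)
  if (length(lines) < 3) stop("GENEPOP file too short", call. = FALSE)

  title <- lines[1]
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3) {
    stop("no 'Pop' separator found after the locus names", call. = FALSE)
  }

  locus_lines <- lines[2:(first_pop - 1)]
  locus_ids <- unlist(strsplit(locus_lines, ","))
  locus_ids <- trimws(locus_ids)
  locus_ids <- locus_ids[nzchar(locus_ids)]
  L <- length(locus_ids)
  if (L < 1) stop("no locus names declared", call. = FALSE)
  if (anyDuplicated(locus_ids)) {
    stop("duplicated locus names in header", call. = FALSE)
  }

  pop_starts <- which(is_pop)
  n_blocks <- length(pop_starts)
  if (n_blocks > 1) {
    warning(sprintf(
      "%d 'Pop' blocks found; individuals merged into a single sample",
      n_blocks), call. = FALSE)
  }

  ids <- character(0)
  rows <- list()
  width <- NA_integer_  # characters per genotype token, detected per file
  for (ln in seq(first_pop, length(lines))) {
    line <- lines[ln]
    if (is_pop[ln] || !nzchar(trimws(line))) next
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0) {
      stop(sprintf("line %d: expected 'id , genotypes...' (no comma found)",
                   ln), call. = FALSE)
    }
    id <- trimws(substr(line, 1, comma - 1))
    geno_part <- substr(line, comma + 1, nchar(line))
    toks <- strsplit(trimws(geno_part), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (is.na(width)) {
      w <- unique(nchar(toks))
      if (length(w) != 1 || !w %in% c(4L, 6L)) {
        stop(sprintf(
          "line %d: genotype tokens must all be 4 or 6 characters wide", ln),
          call. = FALSE)
      }
      width <- w
    }
    if (any(nchar(toks) != width)) {
      stop(sprintf("line %d: genotype token width differs from %d", ln, width),
           call. = FALSE)
    }
    if (length(toks) != L) {
      stop(sprintf("line %d: %d genotypes found but %d loci declared",
                   ln, length(toks), L), call. = FALSE)
    }
    half <- width / 2L
    a1 <- suppressWarnings(as.integer(substr(toks, 1L, half)))
    a2 <- suppressWarnings(as.integer(substr(toks, half + 1L, width)))
    if (anyNA(a1) || anyNA(a2)) {
      stop(sprintf("line %d: non-numeric allele code", ln), call. = FALSE)
    }
    if (any(a1 > 2L) || any(a2 > 2L)) {
      stop(sprintf(
        "line %d: allele code > 2; only biallelic SNP data are supported",
        ln), call. = FALSE)
    }
    dos <- (a1 == 1L) + (a2 == 1L)
    dos[a1 == 0L | a2 == 0L] <- NA_integer_
    ids <- c(ids, id)
    rows[[length(rows) + 1L]] <- as.integer(dos)
  }

  # every Pop separator must introduce at least one individual
  body_nonempty <- nzchar(trimws(lines)) & !is_pop
  for (k in seq_along(pop_starts)) {
    blk_end <- if (k < n_blocks) pop_starts[k + 1] - 1 else length(lines)
    blk <- seq(pop_starts[k] + 1, length.out = max(0, blk_end - pop_starts[k]))
    if (!any(body_nonempty[blk])) {
      stop(sprintf("empty 'Pop' block at line %d", pop_starts[k]),
           call. = FALSE)
    }
  }
  if (length(rows) == 0) stop("no individuals found", call. = FALSE)

  genotype_matrix(do.call(rbind, rows),
                  individual_ids = ids,
                  locus_ids = locus_ids,
                  population_label = title)
}

#' Write a genotype matrix as GENEPOP text
#'
#' Emits the dialect understood by [read_genepop()]: reading the output back
#' reproduces the input matrix exactly. Missing genotypes are written as
#' `0000` (2-digit codes) or `000000` (3-digit codes).
#'
#' @param matrix a [genotype_matrix()].
#' @param allele_width 2 or 3 digits per allele code.
#' @param path optional file path; when `NULL` the lines are returned
#'   invisibly as a character vector.
#' @return character vector of lines, invisibly.
#' @export
write_genepop <- function(matrix, allele_width = 2L, path = NULL) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (!allele_width %in% c(2L, 3L)) {
    stop("allele_width must be 2 or 3", call. = FALSE)
  }
  if (n_ind(matrix) < 1L) stop("refusing to write an empty sample",
                               call. = FALSE)
  fmt <- if (allele_width == 2L) "%02d%02d" else "%03d%03d"
  codes <- c(sprintf(fmt, 2L, 2L),   # dosage 0
             sprintf(fmt, 1L, 2L),   # dosage 1
             sprintf(fmt, 1L, 1L))   # dosage 2
  missing_code <- sprintf(fmt, 0L, 0L)
  d <- matrix$dosage
  tok <- base::matrix(missing_code, nrow(d), ncol(d))
  ok <- !is.na(d)
  tok[ok] <- codes[d[ok] + 1L]
  body <- paste(matrix$individual_ids, ",",
                apply(tok, 1, paste, collapse = " "))
  out <- c(matrix$population_label, matrix$locus_ids, "Pop", body)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
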