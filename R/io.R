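# Shared readers/writers. Interchange dialect: TSV (tab, UTF-8) with
# '#'-prefixed provenance header lines; FASTA wrapped at 80 columns;
# coordinates 0-based half-open.

#' Run configuration for provenance headers
#'
#' Bundles stage parameters (seeds, thresholds, windows, gates) so every
#' output file can carry a provenance header naming the tool version, a
#' config hash and the seeds used.
#'
#' @param ... named scalar parameters; every stochastic stage should pass an
#'   explicit `seed`.
#' @return object of class `drscan_config`.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) && (is.null(names(cfg)) || any(names(cfg) == "")))
    stop("all run_config() parameters must be named")
  structure(cfg, class = "drscan_config")
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                                character(1)), sep = "=", collapse = ";")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

provenance_header <- function(config = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("drscan")),
                  error = function(e) "0.0.0")
  lines <- c(sprintf("# drscan %s", ver))
  if (!is.null(config)) {
    lines <- c(lines, sprintf("# config_hash=%s", config_hash(config)))
    seeds <- config[grepl("seed", names(config))]
    if (length(seeds))
      lines <- c(lines, paste0("# ", paste(names(seeds), unlist(seeds),
                                           sep = "=", collapse = " ")))
  }
  lines
}

#' Read a FASTA file
#'
#' @param path FASTA file (gzip transparently handled).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  setNames(as.character(x), names(x))
}

#' Write sequences to FASTA (80-column wrap)
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (gzip transparently handled).
#' @return data.frame with columns `id`, `sequence`, `quality` (Phred+33
#'   string); sequence and quality lengths are validated per record.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # validate 4-line record structure up front: the downstream parser does
  # not reliably reject quality lines of the wrong length
  con <- gzfile(path, "rt")
  lines <- readLines(con)
  close(con)
  if (!length(lines)) stop("empty FASTQ file: ", path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ in ", path, ": line count not a multiple of 4")
  i1 <- seq(1L, length(lines), 4L)
  bad <- which(!startsWith(lines[i1], "@") | !startsWith(lines[i1 + 2L], "+") |
                 nchar(lines[i1 + 1L]) != nchar(lines[i1 + 3L]))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " in ", path,
         " (header/separator tags or sequence/quality lengths)")
  x <- tryCatch(
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")),
    error = function(e) stop("malformed FASTQ in ", path, ": ", conditionMessage(e)))
  df <- data.frame(id = names(x),
                   sequence = as.character(x),
                   quality = as.character(Biostrings::quality(x)),
                   stringsAsFactors = FALSE, row.names = NULL)
  bad <- which(nchar(df$sequence) != nchar(df$quality))
  if (length(bad))
    stop("FASTQ record ", bad[1L], " has mismatched sequence/quality lengths")
  df
}

#' Decode a Phred+33 quality string to integer Q-scores
#'
#' @param qual character vector of quality strings.
#' @return list of integer vectors.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Write a data frame as TSV with a provenance header
#'
#' @param df data frame.
#' @param path output path.
#' @param config optional [run_config()] serialized into the header.
#' @export
write_tsv <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (or any '#'-commented TSV)
#'
#' @param path input path.
#' @param required_cols columns that must be present; a missing column is a
#'   schema error naming the column.
#' @return data.frame.
#' @export
read_tsv <- function(path, required_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L && ncol(df) == 0L) stop("empty TSV file: ", path)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("TSV ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read a receptor-by-sample count table from TSV
#'
#' Expects a `receptor` column plus one integer column per sample.
#'
#' @param path input path.
#' @return integer matrix, receptors in rows.
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv(path, required_cols = "receptor")
  m <- as.matrix(df[setdiff(names(df), "receptor")])
  storage.mode(m) <- "integer"
  rownames(m) <- df$receptor
  if (any(is.na(m)) || any(m < 0L)) stop("counts must be non-negative integers")
  m
}

#' Write a count matrix as TSV
#' @param counts integer matrix with receptor rownames.
#' @param path output path.
#' @param config optional [run_config()].
#' @export
write_counts_tsv <- function(counts, path, config = NULL) {
  df <- data.frame(receptor = rownames(counts), counts, check.names = FALSE)
  write_tsv(df, path, config)
}

#' Read atoms from a PDB file (first model, ATOM/HETATM)
#'
#' @param path PDB file.
#' @param keep_hetatm keep HETATM records (default FALSE).
#' @return data.frame with columns element, atom name, residue name/number,
#'   chain and coordinates (Angstrom), ready for [assign_radii()].
#' @export
read_pdb_atoms <- function(path, keep_hetatm = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  if (!keep_hetatm) a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms read from ", path)
  elem <- toupper(trimws(a$elesy))
  blank <- !nzchar(elem) | is.na(elem)
  # fall back to the first alphabetic character of the atom name
  elem[blank] <- substr(gsub("[^A-Za-z].*", "", gsub("^[0-9]*", "", a$elety[blank])), 1L, 1L)
  data.frame(element = elem, name = trimws(a$elety), resname = trimws(a$resid),
             resno = a$resno, chain = a$chain,
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

#' Read per-residue secondary-structure assignments from TSV
#'
#' Expects columns `residue` (number) and `ss` (one-letter code from
#' H, G, I, E, B, T, C).
#'
#' @param path input path.
#' @return character vector of per-residue codes in residue order.
#' @export
read_ss_tsv <- function(path) {
  df <- read_tsv(path, required_cols = c("residue", "ss"))
  df$ss[order(df$residue)]
}

#' Read BED-like footprint records (transcript, start, length)
#'
#' @param path TSV with columns `transcript`, `start` (0-based 5' offset in
#'   the CDS) and `length` (nt).
#' @return data.frame of footprint records.
#' @export
read_bedlike <- function(path) {
  df <- read_tsv(path, required_cols = c("transcript", "start", "length"))
  if (any(df$start < 0L)) stop("footprint start offsets must be >= 0")
  if (any(df$length <= 0L)) stop("footprint lengths must be > 0")
  df
}
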