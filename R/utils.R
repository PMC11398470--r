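# Shared internal helpers.

# Accept a character vector, DNAStringSet, or FASTQ path and return a plain
# uppercase character vector of read sequences.
.as_read_seqs <- function(reads) {
  if (is(reads, "DNAStringSet")) return(as.character(reads))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads, ignore.case = TRUE)) {
    return(as.character(readDNAStringSet(reads, format = "fastq")))
  }
  toupper(as.character(reads))
}

# Minimal FASTQ writer (constant qualities; the pipeline never uses base
# qualities). gzip-compresses when the path ends in .gz.
.write_fastq <- function(seqs, path, ids = NULL) {
  n <- length(seqs)
  if (is.null(ids)) ids <- sprintf("read%07d", seq_len(n))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (n > 0L) {
    rec <- paste0("@", ids, "\n", seqs, "\n+\n",
                  strrep("I", nchar(seqs)))
    writeLines(rec, con)
  }
  invisible(path)
}

# Random fixed-length DNA sequences from the session RNG.
.random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Deterministic library column keys.
.lib_key <- function(sample_id, channel) paste(sample_id, channel, sep = ".")

.pair_key <- function(bc_red, bc_ir) paste(bc_red, bc_ir, sep = "|")

.check_manifest <- function(manifest) {
  need <- c("sample_id", "condition", "replicate", "channel")
  if (!all(need %in% colnames(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(paste(manifest$sample_id, manifest$channel)))
    stop("duplicate (sample_id, channel) rows in manifest")
  if (!all(manifest$channel %in% c("red", "ir")))
    stop("manifest channel must be 'red' or 'ir'")
  invisible(manifest)
}
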