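# File-format helpers: FASTA via Biostrings, plates as CSV (rows = wells,
# columns = replicates), clone-identity tables as TSV.

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @param type `"protein"` or `"dna"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  set <- if (type == "protein") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param type `"protein"` or `"dna"`.
#' @export
write_fasta <- function(sequences, path, type = c("protein", "dna")) {
  type <- match.arg(type)
  set <- if (type == "protein") Biostrings::AAStringSet(sequences)
         else Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write plate readings to CSV
#'
#' One row per well (A1..H12 per plate), one `rep<k>` column per replicate,
#' plus `sample_id`, `substrate_class`, `plate_id`, `substrate`.
#'
#' @param readings Long-format readings (see [simulate_plate()]).
#' @param path Output CSV path.
#' @export
write_plate_csv <- function(readings, path) {
  key <- paste(readings$sample_id, readings$substrate_class,
               readings$plate_id, readings$well, sep = "\r")
  first <- !duplicated(key)
  wide <- readings[first, c("sample_id", "substrate_class", "plate_id",
                            "well", "substrate")]
  for (r in sort(unique(readings$replicate))) {
    sub <- readings[readings$replicate == r, ]
    subkey <- key[readings$replicate == r]
    wide[[paste0("rep", r)]] <- sub$od[match(key[first], subkey)]
  }
  write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Read plate readings from CSV
#'
#' Inverse of [write_plate_csv()].
#'
#' @param path CSV path.
#' @return Long-format readings data.frame.
#' @export
read_plate_csv <- function(path) {
  wide <- read.csv(path, stringsAsFactors = FALSE)
  repcols <- grep("^rep[0-9]+$", names(wide), value = TRUE)
  if (length(repcols) == 0) stopf("no replicate columns (rep1, rep2, ...) found")
  out <- list()
  for (rc in repcols) {
    out[[rc]] <- data.frame(
      sample_id = wide$sample_id, substrate_class = wide$substrate_class,
      plate_id = wide$plate_id,
      replicate = as.integer(sub("^rep", "", rc)),
      well = wide$well, substrate = wide$substrate, od = wide[[rc]],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
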