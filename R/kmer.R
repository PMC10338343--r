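# Fraction of transcripts sharing at least one k-mer with transposon
# consensus sequences.

dna_revcomp <- function(x) {
  vapply(strsplit(toupper(x), "", fixed = TRUE), function(s) {
    paste(rev(unname(DNA_COMPLEMENT[s])), collapse = "")
  }, character(1))
}

kmer_set <- function(seqs, k) {
  out <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    starts <- seq_len(n - k + 1L)
    substring(s, starts, starts + k - 1L)
  }))
  out <- unique(out)
  out[!grepl("N", out, fixed = TRUE)]  # ambiguity codes excluded
}

#' Fraction of transcripts sharing at least one k-mer with a consensus set
#'
#' For each k, the exact k-mer set of the consensus sequences is
#' intersected with every transcript's k-mers; a transcript counts once if
#' it contains any shared k-mer. The fraction is monotone non-increasing
#' in k.
#'
#' @param transcripts Character vector of transcript sequences (or tibble
#'   with columns `name`, `sequence`).
#' @param consensus Character vector of consensus sequences.
#' @param k_values Integer vector of k values.
#' @param strand_mode `"sense"` (default): sense-strand consensus k-mers
#'   against sense-strand transcripts; `"both"`: consensus k-mers from
#'   both strands.
#' @return Tibble per k: `k`, `n_transcripts`, `n_with_shared_kmer`,
#'   `fraction`, `strand_mode`.
#' @export
shared_kmer_fraction <- function(transcripts, consensus, k_values,
                                 strand_mode = c("sense", "both")) {
  strand_mode <- match.arg(strand_mode)
  if (is.data.frame(transcripts)) transcripts <- transcripts$sequence
  transcripts <- toupper(chartr("u", "U", transcripts))
  transcripts <- chartr("U", "T", transcripts)
  consensus <- chartr("U", "T", toupper(consensus))
  if (length(transcripts) == 0 || length(consensus) == 0) {
    abort("transcripts and consensus must be non-empty")
  }
  cons <- if (strand_mode == "both") {
    c(consensus, dna_revcomp(consensus))
  } else consensus
  map(sort(unique(as.integer(k_values))), function(k) {
    cset <- kmer_set(cons, k)
    hit <- if (length(cset) == 0) {
      rep(FALSE, length(transcripts))
    } else {
      vapply(transcripts, function(tx) {
        any(kmer_set(tx, k) %in% cset)
      }, logical(1), USE.NAMES = FALSE)
    }
    tibble(k = k, n_transcripts = length(transcripts),
           n_with_shared_kmer = sum(hit),
           fraction = mean(hit), strand_mode = strand_mode)
  }) |>
    list_rbind()
}
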