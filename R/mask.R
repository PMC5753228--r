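#' Mask low-complexity regions by sliding-window entropy
#'
#' Two-threshold sliding-window Shannon-entropy segmentation in the style of
#' the classic SEG filter. Every window of `window` residues gets a Shannon
#' entropy (bits) from its residue composition. Windows below the trigger
#' threshold nucleate a low-complexity segment; the segment extends over
#' adjacent windows while their entropy stays below the extension threshold;
#' overlapping segments merge. Every position covered by a window of a
#' triggered segment is replaced by lowercase `"x"`.
#'
#' Windows that already contain the mask symbol are exempt from triggering
#' and extension, so masking an already-masked sequence changes nothing
#' (masking is idempotent). Sequences shorter than one window are returned
#' unchanged.
#'
#' @param sequence Character vector of amino-acid sequences (may contain
#'   `"x"` from a previous pass).
#' @param window Window length in residues.
#' @param trigger_entropy Entropy (bits) below which a window nucleates a
#'   segment.
#' @param extension_entropy Entropy (bits) below which adjacent windows
#'   extend a segment.
#' @return Character vector of the same length with low-complexity positions
#'   masked as `"x"`.
#' @examples
#' mask_low_complexity(strrep("K", 36))
#' mask_low_complexity("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
#' @export
mask_low_complexity <- function(sequence, window = 12L,
                                trigger_entropy = 2.2,
                                extension_entropy = 2.5) {
  vapply(sequence, mask_one, character(1),
         window = as.integer(window),
         trigger = trigger_entropy, extension = extension_entropy,
         USE.NAMES = FALSE)
}

mask_one <- function(s, window, trigger, extension) {
  n <- nchar(s)
  if (n < window) return(s)
  ch <- seq_chars(s)
  ent <- window_entropy(ch, window)
  clean <- !vapply(seq_along(ent), function(i) {
    any(ch[i:(i + window - 1)] == MASK_CHAR)
  }, logical(1))
  eligible <- clean & ent < extension
  trig <- clean & ent < trigger
  if (!any(trig)) return(s)

  # segments = maximal runs of eligible windows containing >= 1 trigger
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    if (!any(trig[starts[k]:ends[k]])) next
    ch[starts[k]:(ends[k] + window - 1)] <- MASK_CHAR
  }
  paste(ch, collapse = "")
}

# Shannon entropy (bits) of each length-`window` window, by rolling counts.
window_entropy <- function(ch, window) {
  n <- length(ch)
  nw <- n - window + 1
  counts <- table(factor(ch[1:window], levels = unique(ch)))
  lv <- names(counts)
  cnt <- as.integer(counts)
  names(cnt) <- lv
  # grow the count vector lazily as new letters enter
  ent <- numeric(nw)
  entropy_of <- function(cnt) {
    p <- cnt[cnt > 0] / window
    -sum(p * log2(p))
  }
  ent[1] <- entropy_of(cnt)
  if (nw > 1) {
    for (i in 2:nw) {
      out_ch <- ch[i - 1]
      in_ch <- ch[i + window - 1]
      cnt[out_ch] <- cnt[out_ch] - 1L
      if (is.na(cnt[in_ch])) cnt[in_ch] <- 0L
      cnt[in_ch] <- cnt[in_ch] + 1L
      ent[i] <- entropy_of(cnt)
    }
  }
  ent
}

#' Mask low-complexity regions across a protein table
#'
#' Fills the `masked_sequence` column of a protein tibble using
#' [mask_low_complexity()] with the configuration's masking parameters.
#'
#' @param proteins A protein tibble.
#' @param config A [refinement_config()].
#' @return The protein tibble with `masked_sequence` populated.
#' @export
mask_proteins <- function(proteins, config = refinement_config()) {
  config <- as_refinement_config(config)
  validate_proteins(proteins)
  proteins$masked_sequence <- mask_low_complexity(
    proteins$sequence,
    window = config$seg_window,
    trigger_entropy = config$seg_trigger,
    extension_entropy = config$seg_extension
  )
  proteins
}
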