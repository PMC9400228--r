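# Transcript-coordinate machinery. All genomic intervals are 0-based
# half-open [start, end); transcript coordinates count spliced bases from the
# 5' end of the mature transcript, so they are strand-aware.

# Order exon rows 5'->3' along the transcript.
exons_tx_order <- function(exons, strand) {
  exons <- exons[order(exons$start), , drop = FALSE]
  if (identical(strand, "-")) exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  exons
}

tx_length <- function(exons) sum(exons$end - exons$start)

# Map genomic base positions (0-based) to transcript coordinates.
# Positions falling outside every exon map to NA.
genomic_to_tx <- function(pos, exons, strand) {
  ex <- exons_tx_order(exons, strand)
  widths <- ex$end - ex$start
  offsets <- cumsum(c(0, widths[-length(widths)]))
  out <- rep(NA_real_, length(pos))
  for (i in seq_len(nrow(ex))) {
    hit <- !is.na(pos) & pos >= ex$start[i] & pos < ex$end[i]
    if (!any(hit)) next
    out[hit] <- if (identical(strand, "-")) {
      offsets[i] + (ex$end[i] - 1 - pos[hit])
    } else {
      offsets[i] + (pos[hit] - ex$start[i])
    }
  }
  out
}

# Inverse mapping: transcript coordinate -> genomic base (0-based).
tx_to_genomic <- function(txpos, exons, strand) {
  ex <- exons_tx_order(exons, strand)
  widths <- ex$end - ex$start
  offsets <- cumsum(c(0, widths[-length(widths)]))
  total <- sum(widths)
  out <- rep(NA_real_, length(txpos))
  for (i in seq_len(nrow(ex))) {
    hit <- !is.na(txpos) & txpos >= offsets[i] & txpos < offsets[i] + widths[i]
    if (!any(hit)) next
    within <- txpos[hit] - offsets[i]
    out[hit] <- if (identical(strand, "-")) ex$end[i] - 1 - within else ex$start[i] + within
  }
  if (any(!is.na(txpos) & (txpos < 0 | txpos >= total))) {
    stop("transcript coordinate outside transcript of length ", total)
  }
  out
}

# Assign a transcript coordinate to the tripartite 5'UTR | CDS | 3'UTR axis.
# Returns region label, the position normalized within its region in [0,1),
# and the pooled axis coordinate in [0,3) (unit length per region).
region_of_tx <- function(txpos, utr5_len, cds_len, utr3_len) {
  total <- utr5_len + cds_len + utr3_len
  stopifnot(all(is.na(txpos) | (txpos >= 0 & txpos < total)))
  region <- dplyr::case_when(
    is.na(txpos) ~ NA_character_,
    txpos < utr5_len ~ "utr5",
    txpos < utr5_len + cds_len ~ "cds",
    TRUE ~ "utr3"
  )
  rel <- dplyr::case_when(
    is.na(txpos) ~ NA_real_,
    region == "utr5" ~ txpos / max(utr5_len, 1),
    region == "cds" ~ (txpos - utr5_len) / max(cds_len, 1),
    TRUE ~ (txpos - utr5_len - cds_len) / max(utr3_len, 1)
  )
  axis <- dplyr::case_when(
    is.na(txpos) ~ NA_real_,
    region == "utr5" ~ rel,
    region == "cds" ~ 1 + rel,
    TRUE ~ 2 + rel
  )
  tibble::tibble(region = region, rel_pos = rel, axis_pos = axis)
}

# Retrieve one gene row (as a one-row tibble) by id, with a clear error.
gene_row <- function(genes, gene_id) {
  g <- genes[genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1L) stop("gene '", gene_id, "' not found (or duplicated) in gene models")
  g
}
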