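#' Simulate MeRIP-seq-like m6A peak intervals
#'
#' Emits one genomic interval per true mRNA m6A site, centered on the site's
#' genomic position with a configurable width (default 100 bp, matching the
#' ~100 nt fragmentation used in MeRIP-seq), BED-style 0-based half-open with
#' the strand copied from the source gene.
#'
#' @param truth Output of [simulate_truth()].
#' @param genes Gene models tibble.
#' @param width Peak width in bp.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#'   Sites falling outside their transcript abort with a report naming them.
#' @export
simulate_peaks <- function(truth, genes, width = 100) {
  sites <- truth$sites
  if (nrow(sites) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          name = character(), score = numeric(), strand = character()))
  }
  sites <- dplyr::left_join(sites, genes, by = "gene_id")
  bad <- sites$tx_pos < 0 | sites$tx_pos >= sites$tx_length | is.na(sites$tx_length)
  if (any(bad)) {
    stop("m6A sites outside their transcript: ",
         paste(sites$gene_id[bad], sites$site_index[bad], sep = ":", collapse = ", "))
  }
  gpos <- purrr::pmap_dbl(
    list(sites$tx_pos, sites$exons, sites$strand),
    function(p, ex, st) tx_to_genomic(p, ex, st)
  )
  half <- floor(width / 2)
  tibble::tibble(
    chrom = sites$chrom,
    start = pmax(gpos - half, 0),
    end = pmax(gpos - half, 0) + width,
    name = paste0(sites$gene_id, "_site", sites$site_index),
    score = 0,
    strand = sites$strand
  )
}

#' Simulate a complete study
#'
#' Runs the full generator: annotation, ground truth, two-channel probe
#' intensities and peak intervals, under one seed, giving a self-contained
#' synthetic study with 3 tumor vs 3 normal samples by default.
#'
#' @param config A [sim_config()].
#' @return A list with `config`, `genes`, `circs`, `truth`, `probes`, `peaks`.
#' @export
#' @examples
#' sim <- simulate_study(sim_config(n_genes = 10, seed = 1))
#' head(sim$probes)
simulate_study <- function(config = sim_config()) {
  ann <- simulate_annotation(config)
  truth <- simulate_truth(ann, config)
  probes <- simulate_intensities(truth, config)
  peaks <- simulate_peaks(truth, ann$genes, width = config$peak_width)
  list(config = config, genes = ann$genes, circs = ann$circs,
       truth = truth, probes = probes, peaks = peaks)
}
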