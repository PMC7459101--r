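#' Human genome definition (GRCh38, approximate)
#'
#' Chromosome lengths and centromere midpoints for chr1-22 and chrX,
#' rounded to 0.1 Mbp from public GRCh38 cytogenetic coordinates. These
#' are reference values for intra-chromosomal distance calculations and
#' for placing simulated genes; sub-Mbp accuracy is not required by any
#' analysis in the package (distances are interpreted against a 50 Mbp
#' threshold).
#'
#' @return Tibble: `chromosome`, `length_bp`, `centromere_bp`.
#' @export
genome_definition <- function() {
  tibble::tibble(
    chromosome = c(paste0("chr", 1:22), "chrX"),
    length_bp = 1e6 * c(249.0, 242.2, 198.3, 190.2, 181.5, 170.8, 159.3,
                        145.1, 138.4, 133.8, 135.1, 133.3, 114.4, 107.0,
                        102.0, 90.3, 83.3, 80.4, 58.6, 64.4, 46.7, 50.8,
                        156.0),
    centromere_bp = 1e6 * c(123.4, 93.9, 90.9, 50.0, 48.8, 59.8, 60.1,
                            45.2, 43.0, 39.8, 53.4, 35.5, 17.7, 17.2,
                            19.0, 36.8, 25.1, 18.5, 26.2, 28.1, 12.0,
                            15.0, 61.0)
  )
}

#' Annotation of the twelve myogenic loci of interest
#'
#' Gene-body coordinates (approximate GRCh38) for the loci whose nuclear
#' position and expression are jointly analyzed in the myoblast/myotube
#' design: muscle structural and regulatory genes plus the stable controls
#' HPRT1, NCAM1 and ACTN3. `window_mbp` is the default neighbourhood
#' width used for the K_mean analysis of each gene (0.95 Mbp for most
#' loci, 1.5 Mbp for ACTN2, HPRT1, MYF5 and MYF6, whose sparser
#' neighbourhoods need the wider window).
#'
#' @return Tibble: `gene_symbol`, `chromosome`, `gene_start_bp`,
#'   `gene_end_bp`, `probe_id`, `window_mbp`.
#' @export
goi_annotation <- function() {
  tibble::tibble(
    gene_symbol = c("MYH2", "VCAM1", "DPP4", "NCAM1", "MYOG", "ACTN2",
                    "ACTN3", "DES", "MYF5", "MYF6", "HPRT1", "CDH15"),
    chromosome = c("chr17", "chr1", "chr2", "chr11", "chr1", "chr1",
                   "chr11", "chr2", "chr12", "chr12", "chrX", "chr16"),
    gene_start_bp = c(10424465L, 100719742L, 161992245L, 112961420L,
                      203052256L, 236686454L, 66546395L, 219418377L,
                      80707588L, 80717156L, 134460165L, 89172534L),
    gene_end_bp = c(10456058L, 100739045L, 162074215L, 113278436L,
                    203055166L, 236764631L, 66563329L, 219426735L,
                    80710391L, 80719240L, 134500668L, 89196563L),
    probe_id = c("MYH2", "VCAM1", "DPP4", "NCAM1", "MYOG", "ACTN2",
                 "ACTN3", "DES", "MYF5", "MYF6", "HPRT1", "CDH15"),
    window_mbp = c(0.95, 0.95, 0.95, 0.95, 0.95, 1.5,
                   0.95, 0.95, 1.5, 1.5, 1.5, 0.95)
  )
}
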