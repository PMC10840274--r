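#' Assign gene-level allele-specific copy numbers from segments
#'
#' Each gene receives the (major, minor) copy numbers of the segment with
#' the greatest overlap with the gene body, overlap being measured in bases
#' inside the gene (0-based half-open coordinates). Ties are broken in
#' favor of the segment with the smaller start. Genes with no intersecting
#' segment in a sample are marked missing for that sample; a chromosome
#' present in the annotation but absent from a sample's segments yields
#' missing values, not an error. Overlapping segments within one sample and
#' chromosome are an error.
#'
#' @param segments data.frame from [read_segments()].
#' @param genes data.frame from [read_gene_annotation()].
#' @return a [copy_number_profile()] over all annotated genes and all
#'   samples present in `segments`.
#' @export
assign_gene_cn <- function(segments, genes) {
  check(is.data.frame(segments) && nrow(segments) > 0L, "no segments given")
  check(is.data.frame(genes) && nrow(genes) > 0L, "no genes given")
  check(all(segments$start < segments$end), "malformed segment interval")
  check(all(genes$start < genes$end), "malformed gene interval")
  samples <- unique(as.character(segments$sample_id))
  gid <- as.character(genes$gene_id)
  major <- matrix(NA_real_, nrow(genes), length(samples),
                  dimnames = list(gid, samples))
  minor <- major
  for (s in samples) {
    seg_s <- segments[segments$sample_id == s, , drop = FALSE]
    for (chr in unique(seg_s$chrom)) {
      seg <- seg_s[seg_s$chrom == chr, , drop = FALSE]
      seg <- seg[order(seg$start), , drop = FALSE]
      if (nrow(seg) > 1L) {
        check(all(seg$start[-1L] >= seg$end[-nrow(seg)]),
              "overlapping segments in sample %s, chromosome %s", s, chr)
      }
      gi <- which(genes$chrom == chr)
      for (i in gi) {
        ov <- pmin(seg$end, genes$end[i]) - pmax(seg$start, genes$start[i])
        hit <- which(ov > 0)
        if (length(hit) == 0L) next
        # greatest within-gene overlap; tie -> smaller segment start
        best <- hit[order(-ov[hit], seg$start[hit])][1L]
        major[i, s] <- seg$major[best]
        minor[i, s] <- seg$minor[best]
      }
    }
  }
  copy_number_profile(major, minor)
}

#' Tumor purity from the TP53 variant allele frequency
#'
#' In tumors where essentially all cancer cells carry a homozygous truncal
#' TP53 mutation, the variant allele frequency (VAF) at the TP53 locus,
#' together with the locus total copy number, determines the tumor cell
#' fraction:
#' \deqn{purity = 2 / ((CN/VAF) - (CN - 2)).}
#' Estimates above 1 (possible under VAF noise) are clamped to 1 with a
#' flag.
#'
#' @param cn_total total copy number at the TP53 locus (> 0).
#' @param vaf variant allele frequency in (0, 1].
#' @return list with `purity` (in (0, 1]), `clamped` flag, and the inputs
#'   `cn_used`, `vaf_used`.
#' @export
purity_from_tp53 <- function(cn_total, vaf) {
  check(is.numeric(cn_total) && length(cn_total) == 1L && cn_total > 0,
        "cn_total must be a positive scalar")
  check(is.numeric(vaf) && length(vaf) == 1L && vaf > 0 && vaf <= 1,
        "vaf must be in (0, 1]")
  denom <- (cn_total / vaf) - (cn_total - 2)
  check(denom > 0, "inconsistent CN/VAF: nonpositive denominator")
  purity <- 2 / denom
  clamped <- purity > 1
  if (clamped) purity <- 1
  check(purity > 0, "nonpositive purity from CN=%g, VAF=%g", cn_total, vaf)
  list(purity = purity, clamped = clamped, cn_used = cn_total, vaf_used = vaf)
}
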