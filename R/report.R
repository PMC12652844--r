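# Top-k reporting in the column layouts of published effect tables.

#' Top-k effects in publication table layout
#'
#' Ranks an effect table by `log10_inv_p` (descending, ties by chromosome,
#' position, SNP id) and reformats the leading `k` rows of one effect type:
#' additive rows are decomposed into positive/negative allele, allelic
#' effect and allele frequency; dominance rows list the three dominance
#' values with genotype frequencies; pairwise rows list both SNPs, the
#' effect type and value.
#'
#' @param records a scan result.
#' @param type one of `"A"`, `"D"`, `"AxA"`, `"AxD"`, `"DxA"`, `"DxD"`.
#' @param k number of rows to keep (default 20).
#' @return Data frame in the corresponding layout.
#' @export
top_effects <- function(records, type = "A", k = 20) {
  stopifnot(type %in% c("A", "D", "AxA", "AxD", "DxA", "DxD"))
  tb <- records[records$effect_type == type & !is.na(records$log10_inv_p), ,
                drop = FALSE]
  tb <- utils::head(tb, k)
  if (!nrow(tb)) return(tb)
  if (type == "A") {
    pos_is_1 <- tb$a1 >= tb$a2
    data.frame(snp = tb$snp_id, chr = tb$chr, pos = tb$pos,
               alpha = tb$value,
               al_pos = ifelse(pos_is_1, "1", "2"),
               ae_pos = ifelse(pos_is_1, tb$a1, tb$a2),
               f_pos = ifelse(pos_is_1, tb$p1, tb$p2),
               al_neg = ifelse(pos_is_1, "2", "1"),
               ae_neg = ifelse(pos_is_1, tb$a2, tb$a1),
               f_neg = ifelse(pos_is_1, tb$p2, tb$p1),
               log10invp = tb$log10_inv_p, stringsAsFactors = FALSE)
  } else if (type == "D") {
    data.frame(snp = tb$snp_id, chr = tb$chr, pos = tb$pos,
               delta = tb$value,
               d12 = tb$d12, f12 = tb$f12, d11 = tb$d11, f11 = tb$f11,
               d22 = tb$d22, f22 = tb$f22,
               log10invp = tb$log10_inv_p, stringsAsFactors = FALSE)
  } else {
    data.frame(snp1 = tb$snp1, chr1 = tb$chr1, pos1 = tb$pos1,
               snp2 = tb$snp2, chr2 = tb$chr2, pos2 = tb$pos2,
               effect = tb$effect_type, value = tb$value,
               log10invp = tb$log10_inv_p, stringsAsFactors = FALSE)
  }
}

#' Days-open equivalent of a pregnancy-rate difference
#'
#' One percentage point of daughter pregnancy rate corresponds to about
#' four fewer days open, so the days-open advantage of one group over
#' another is `days_per_pct * (mean1 - mean2)`.
#'
#' @param mean1,mean2 group phenotype means (% DPR).
#' @param days_per_pct conversion factor (default 4 days per 1% DPR).
#' @return Days-open difference (positive = fewer days open for group 1).
#' @export
heterosis_days_open <- function(mean1, mean2, days_per_pct = 4) {
  days_per_pct * (mean1 - mean2)
}
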