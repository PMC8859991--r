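#!/usr/bin/env Rscript
# Genomic-feature statistics of the hypomethylated transition probes:
# CGI-relation distribution, odds-ratio enrichment/depletion against the
# array background, and AP-1 / SOX motif-hit overlap.

source("analysis/00_config.R")

ann <- read_probe_annotation(data_path("longitudinal_annotation.tsv"))
filt <- read.delim(out_path("dmp_filtered.tsv"))
hypo <- filt$probe_id[filt$direction == "hypo"]
hyper <- filt$probe_id[filt$direction == "hyper"]

dist <- genomic_distribution(hypo, ann)
write_table_tsv(dist, out_path("hypo_genomic_distribution.tsv"))
cat("genomic distribution of hypomethylated probes:\n")
print(dist, row.names = FALSE)

feats <- c("cgi_relation=open_sea", "cgi_relation=island", "cgi_relation=shore",
           "enhancer", "bivalent", "motif_AP1", "motif_SOX")
enr_hypo <- enrichment_table(hypo, ann, feats)
write_table_tsv(enr_hypo, out_path("hypo_enrichment.tsv"))
cat("\nenrichment of hypomethylated probes vs array background:\n")
print(enr_hypo[, c("feature", "odds_ratio", "ci_low", "ci_high", "p", "call")],
      row.names = FALSE, digits = 3)
if (length(hyper) >= 5) {
  enr_hyper <- enrichment_table(hyper, ann, feats)
  write_table_tsv(enr_hyper, out_path("hyper_enrichment.tsv"))
}

mo <- motif_overlap_fraction(hypo, ann, c("AP1", "SOX"))
cat(sprintf("\nAP-1 motif hits: %d of %d (%.2f%%); AP-1 & SOX: %d (%.2f%%)\n",
            mo$n_overlap, length(hypo), mo$fraction, mo$n_both,
            mo$fraction_both))
write_run_summary(list(ap1_overlap = mo$n_overlap, ap1_fraction = mo$fraction,
                       both_overlap = mo$n_both,
                       both_fraction = mo$fraction_both),
                  out_path("motif_overlap.json"))
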