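#!/usr/bin/env Rscript
# Reproduces the published accuracy aggregates from the bundled per-insert
# benchmark: tissue-category and overall RSP MAPE, signed mean percent error,
# mean residuals per SFOV, the extreme-error insert, and the paired
# Head-vs-Body comparison.
library(dectrsp)

dir.create("results", showWarnings = FALSE)

for (sfov in c("body", "head")) {
  rep <- summarize_evaluation(benchmark_roi_results(sfov))
  out <- file.path("results", paste0("benchmark_", sfov))
  write_evaluation_report(rep, out, metadata = list(source = "bundled benchmark",
                                                    sfov = sfov))
  cat("==", toupper(sfov), "SFOV ==\n")
  print(rep)
  cat("\n")
}

body <- summarize_evaluation(benchmark_roi_results("body"))
rows <- benchmark_roi_results("body")
worst <- rows[which.max(abs(rows$percent_error)), ]
cat(sprintf("Largest Body-SFOV |PE|: %s (%s) at %.2f%%\n",
            worst$insert, worst$phantom, worst$percent_error))

tab <- load_insert_reference()
keep <- !is.na(tab$rsp_mean_head)
p <- paired_t_test(tab$rsp_mean_head[keep], tab$rsp_mean_body[keep])
cat(sprintf("Paired t-test, %d Head/Body RSP-mean pairs: p = %.3f (no significant difference)\n",
            sum(keep), p))
cat("Note: aggregates recomputed from the published (rounded) per-insert percent\n")
cat("errors; the bone-category MAPE computes to 1.126 where the source prints 1.12.\n")
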