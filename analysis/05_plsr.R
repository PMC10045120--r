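#!/usr/bin/env Rscript
# PLSR of the 2 h NADPH:NADP+ ratio on the 14 model protein concentrations,
# fit separately for malignant and non-malignant cells (run analysis scripts
# 01 and 04 first). Reports R2Y, cross-validated Q2, and VIP scores.
library(redoxcell)

mat <- read_expression("results/cohort")
ep <- read.csv("results/endpoints.csv", stringsAsFactors = FALSE)

proteins <- protein_concentrations(mat)
write.csv(data.frame(cell_id = rownames(proteins), proteins),
          "results/protein_concentrations.csv", row.names = FALSE)

pls <- plsr_by_class(proteins, ep, seed = 1)

vip <- do.call(rbind, lapply(names(pls), function(cls) {
  data.frame(class = cls, gene = names(pls[[cls]]$vip),
             vip = unname(pls[[cls]]$vip))
}))
write.csv(vip, "results/vip_scores.csv", row.names = FALSE)

loadings <- do.call(rbind, lapply(names(pls), function(cls) {
  P <- pls[[cls]]$fit$P
  data.frame(class = cls, gene = pls[[cls]]$fit$var_names,
             pc1 = P[, 1], pc2 = if (ncol(P) > 1) P[, 2] else NA_real_)
}))
write.csv(loadings, "results/plsr_loadings.csv", row.names = FALSE)

summ <- lapply(pls, function(m)
  list(components = m$A, r2y = m$r2y, q2 = m$q2[m$A], n_cells = m$n))
if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(summ, "results/plsr_summary.json", auto_unbox = TRUE)
}

for (cls in names(pls)) {
  m <- pls[[cls]]
  top <- sort(m$vip, decreasing = TRUE)[1:5]
  cat(sprintf("%s model: A = %d, R2Y = %.3f, Q2 = %.3f (n = %d)\n",
              cls, m$A, m$r2y, m$q2[m$A], m$n))
  cat("  top VIP:", paste(sprintf("%s (%.2f)", names(top), top),
                          collapse = ", "), "\n")
}
cat("wrote results/vip_scores.csv, results/plsr_loadings.csv,",
    "results/plsr_summary.json, results/protein_concentrations.csv\n")
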