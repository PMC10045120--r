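#' Simulate one ODE model per cell
#'
#' Builds a `cell_model_spec` for every annotated cell, applies it to the
#' base network and pre-equilibrated resting state, doses extracellular
#' beta-lapachone, integrates for 2 h, and summarizes endpoints. Cells are
#' processed in sorted cell-ID order so results are reproducible regardless
#' of input ordering. Unstable runs are retained in the table with
#' `status = "unstable"` and `NA` endpoints; downstream statistics use only
#' stable cells.
#'
#' @param matrix Gene x cell expression matrix covering the mapped genes.
#' @param annotations data.frame with cell_id, patient_id, malignant.
#' @param network Base `redox_network`.
#' @param mapping,constants,linear_maps Configuration tables.
#' @param dose Initial extracellular beta-lapachone (molar).
#' @param base_state Resting state; computed by [equilibrate_network()] when
#'   `NULL`.
#' @param settings Solver settings (default: the network's).
#' @return data.frame: cell_id, patient_id, malignant, h2o2, nadph_ratio,
#'   trx_ratio, gsh_ratio, status.
#' @export
run_cohort <- function(matrix, annotations, network,
                       mapping = read_mapping_config(),
                       constants = read_rate_constants(),
                       linear_maps = read_linear_maps(),
                       dose = 5e-6, base_state = NULL,
                       settings = network$solver) {
  missing <- setdiff(annotations$cell_id, colnames(matrix))
  if (length(missing))
    stop("annotations reference cells absent from the matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  ann <- annotations[order(annotations$cell_id), , drop = FALSE]
  genes <- mapped_genes(mapping)
  means <- cohort_means(matrix[, ann$cell_id, drop = FALSE], genes)
  if (is.null(base_state)) base_state <- equilibrate_network(network)

  rows <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    cid <- ann$cell_id[i]
    expr <- stats::setNames(as.numeric(matrix[genes, cid]), genes)
    spec <- build_cell_model(expr, means, mapping, constants, linear_maps,
                             cell_id = cid, patient_id = ann$patient_id[i],
                             malignant = ann$malignant[i])
    cell <- apply_cell_spec(network, spec, base_state, mapping)
    st <- cell$state
    st["blap_ext"] <- dose
    tr <- simulate_network(cell$network, st, settings, n_out = 25)
    ep <- endpoint_summary(tr)
    rows[[i]] <- data.frame(cell_id = cid, patient_id = ann$patient_id[i],
                            malignant = ann$malignant[i],
                            h2o2 = ep[["h2o2"]],
                            nadph_ratio = ep[["nadph_ratio"]],
                            trx_ratio = ep[["trx_ratio"]],
                            gsh_ratio = ep[["gsh_ratio"]],
                            status = tr$status, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_unstable <- sum(out$status != "stable")
  if (n_unstable > 0)
    message(n_unstable, " of ", nrow(out), " cell simulations were unstable",
            " and are excluded from downstream statistics")
  out
}

#' Two-tailed Welch's t-test
#'
#' Unequal-variance two-sample comparison:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-tailed p-value.
#'
#' @param values_a,values_b Numeric vectors, each with at least two values
#'   and nonzero variance (identical constant groups are permitted and give
#'   t = 0 only when both vary; a degenerate group raises an error naming it).
#' @return List with n_a, n_b, mean_a, mean_b, t, df, p.
#' @export
welch_test <- function(values_a, values_b) {
  chk <- function(x, nm) {
    if (length(x) < 2) stop("group ", nm, " has fewer than 2 values", call. = FALSE)
    if (stats::var(x) == 0) stop("group ", nm, " has zero variance", call. = FALSE)
  }
  chk(values_a, "a"); chk(values_b, "b")
  ht <- stats::t.test(values_a, values_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(n_a = length(values_a), n_b = length(values_b),
       mean_a = mean(values_a), mean_b = mean(values_b),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Box-and-whisker statistics
#'
#' Quartiles with whiskers at `Q3 + 1.5 IQR` and `Q1 - 1.5 IQR`; the center
#' line is the mean.
#'
#' @param values Numeric vector.
#' @return Named vector q1, mean, q3, iqr, whisker_lo, whisker_hi.
#' @export
boxplot_stats <- function(values) {
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(q1 = q[1], mean = mean(values), q3 = q[2], iqr = iqr,
    whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[2] + 1.5 * iqr)
}

#' Per-patient malignant vs non-malignant comparison
#'
#' For each patient with stable cells in both classes, runs Welch's t-test
#' on an endpoint (cytosolic H2O2 by default) between malignant and
#' non-malignant cells; single-class patients are excluded with a warning.
#' Also returns a tidy box-plot table per patient and class.
#'
#' Endpoint H2O2 spans orders of magnitude across heterogeneous cells, so by
#' default the comparison (and the box statistics) are computed on log10
#' concentrations, the scale on which such distributions are near-symmetric;
#' set `log10 = FALSE` to compare raw values.
#'
#' @param endpoints Endpoint table from [run_cohort()].
#' @param response Endpoint column to compare.
#' @param log10 Compare log10-transformed values (default TRUE).
#' @return List with `comparisons` (patient_id, group sizes and means, t, df,
#'   p, significant at two-tailed alpha = 0.05) and `boxplot` (tidy per
#'   patient x class quartile/whisker table).
#' @export
patient_report <- function(endpoints, response = "h2o2", log10 = TRUE) {
  ep <- endpoints[endpoints$status == "stable" & is.finite(endpoints[[response]]), ]
  if (!nrow(ep)) stop("no stable cells", call. = FALSE)
  if (log10) ep[[response]] <- base::log10(ep[[response]])
  comp <- list(); box <- list()
  for (pat in unique(ep$patient_id)) {
    sub <- ep[ep$patient_id == pat, ]
    mal <- sub[[response]][sub$malignant == 1]
    non <- sub[[response]][sub$malignant == 0]
    if (length(mal) < 2 || length(non) < 2) {
      warning("patient ", pat, " lacks both classes; excluded", call. = FALSE)
      next
    }
    wt <- welch_test(mal, non)
    comp[[pat]] <- data.frame(
      patient_id = pat, n_malignant = wt$n_a, n_nonmalignant = wt$n_b,
      mean_malignant = wt$mean_a, mean_nonmalignant = wt$mean_b,
      t = wt$t, df = wt$df, p = wt$p, significant = wt$p < 0.05,
      stringsAsFactors = FALSE)
    for (cls in c(0, 1)) {
      bs <- boxplot_stats(sub[[response]][sub$malignant == cls])
      box[[paste(pat, cls)]] <- data.frame(
        patient_id = pat, malignant = cls, t(bs), stringsAsFactors = FALSE)
    }
  }
  list(comparisons = do.call(rbind, c(comp, list(make.row.names = FALSE))),
       boxplot = do.call(rbind, c(box, list(make.row.names = FALSE))))
}
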