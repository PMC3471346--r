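# ggplot2 views and broom-style summaries of the result types.

#' @export
autoplot.pathway_counts <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("count_a", "count_b"),
                              names_to = "pathway", values_to = "genes")
  long$pathway <- ifelse(long$pathway == "count_a", "term A", "term B")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_title, y = .data$genes,
                                     fill = .data$pathway)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "genes passing both filters",
                  fill = NULL,
                  title = "Pathway contrast by sample") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tf_enrichment <- function(object, ...) {
  df <- mutate(object, neglog_p = -log10(pmax(.data$p_value, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_title,
                                   y = .data$neglog_p)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10]~p),
                  title = "Enrichment of highly expressed regulated genes") +
    ggplot2::theme_minimal()
}

#' @export
tidy.tf_enrichment <- function(x, ...) {
  tibble(
    sample_title = x$sample_title,
    tf = x$tf,
    estimate = ifelse(x$total_high_count > 0,
                      x$high_regulated_count / x$total_high_count, 0),
    statistic = x$high_regulated_count,
    p.value = x$p_value
  )
}

#' @export
glance.tf_enrichment <- function(x, ...) {
  tibble(
    n_samples = nrow(x),
    min_p = if (nrow(x) > 0) min(x$p_value) else NA_real_,
    n_significant = sum(x$p_value < 0.05)
  )
}

#' @export
tidy.pathway_counts <- function(x, ...) {
  tibble(sample_title = rep(x$sample_title, 2),
         term = rep(c("a", "b"), each = nrow(x)),
         genes = c(x$count_a, x$count_b))
}

#' @export
glance.pathway_counts <- function(x, ...) {
  tibble(n_samples = nrow(x),
         total_a = sum(x$count_a), total_b = sum(x$count_b))
}
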