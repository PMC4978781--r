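# Shared fixture loaders and random generators for the test suite.

load_example_tables <- function() {
  list(
    gen = read_item_table(irtlink_example("generating_items.csv")),
    cal1 = read_item_table(irtlink_example("cal1_items.csv")),
    cal2 = read_item_table(irtlink_example("cal2_items.csv")),
    cov1 = suppressWarnings(read_cov_table(irtlink_example("cal1_cov.csv"))),
    cov2 = suppressWarnings(read_cov_table(irtlink_example("cal2_cov.csv"))),
    published = readr::read_csv(
      irtlink_example("published_per_item_links.csv"), show_col_types = FALSE)
  )
}

random_items <- function(n, seed = NULL, c_max = 0.35) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(item_id = as.character(seq_len(n)),
                 a = runif(n, 0.4, 2.5),
                 b = runif(n, -2.5, 2.5),
                 c = runif(n, 0, c_max))
}

random_link <- function() {
  linear_link(runif(1, 0.3, 3), runif(1, -1.5, 1.5))
}
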