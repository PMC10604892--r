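#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Nei-Gojobori Ka/Ks result into a one-row tibble
#'
#' @param x A `qzfp_kaks` object from [nei_gojobori()].
#' @param ... Unused.
#' @return One-row tibble with the site counts, difference counts,
#'   proportions, corrected rates, ratio and selection class.
#' @export
tidy.qzfp_kaks <- function(x, ...) {
  tibble(S = x$S, N = x$N, Sd = x$Sd, Nd = x$Nd, ps = x$ps, pn = x$pn,
         Ks = x$Ks, Ka = x$Ka, ratio = x$ratio,
         selection_class = x$selection_class)
}

#' @rdname tidy.qzfp_kaks
#' @export
glance.qzfp_kaks <- function(x, ...) tidy.qzfp_kaks(x, ...)

#' Tidy a family report into its per-member table
#'
#' @param x A `qzfp_report` from [run_pipeline()].
#' @param ... Unused.
#' @return The per-member tibble (name, group, domain counts,
#'   physicochemical profile, placement).
#' @export
tidy.qzfp_report <- function(x, ...) x$members

#' One-row family-level summary of a report
#'
#' @param x A `qzfp_report` from [run_pipeline()].
#' @param ... Unused.
#' @return One-row tibble: member count, per-group counts, EAR tallies.
#' @export
glance.qzfp_report <- function(x, ...) {
  gc <- x$summary$group_counts
  wide <- setNames(as.list(gc$n), paste0("n_", gc$group))
  dplyr::bind_cols(
    tibble(n_members = x$summary$n_members),
    as_tibble(wide),
    tibble(n_with_ear = x$summary$n_with_ear,
           n_with_lxlxl = x$summary$n_with_lxlxl,
           n_with_dlnp = x$summary$n_with_dlnp)
  )
}
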