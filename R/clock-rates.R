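# Per-chain substitution rates from partitioned clock summaries.

#' Clock summary: mean clock rate and relative partition rates
#'
#' @param mean_clockrate mean clock rate in substitutions per site per
#'   million years (> 0).
#' @param relative_partition_rates named numeric vector of per-chain
#'   rate multipliers (all > 0; by the usual convention they average 1
#'   across partitions, but this is not enforced).
#' @param source free-text provenance.
#' @return object of class `"clock_summary"`.
#' @export
clock_summary <- function(mean_clockrate, relative_partition_rates,
                          source = "") {
  if (!is.numeric(mean_clockrate) || length(mean_clockrate) != 1L ||
      !is.finite(mean_clockrate) || mean_clockrate <= 0)
    stop("'mean_clockrate' must be a single positive number")
  r <- relative_partition_rates
  if (!is.numeric(r) || is.null(names(r)) || any(!is.finite(r)) ||
      any(r <= 0))
    stop("'relative_partition_rates' must be a named positive vector")
  structure(list(mean_clockrate = mean_clockrate,
                 relative_partition_rates = r, source = source),
            class = "clock_summary")
}

#' @export
print.clock_summary <- function(x, ...) {
  cat(sprintf("<clock_summary> mean clock rate %g subs/site/Ma\n",
              x$mean_clockrate))
  cat("  relative partition rates:",
      paste(sprintf("%s = %g", names(x$relative_partition_rates),
                    x$relative_partition_rates), collapse = ", "), "\n")
  invisible(x)
}

#' Read a clock summary from a parameter-summary table
#'
#' Parses the whitespace/tab-delimited parameter summaries written by
#' common Bayesian phylogenetics programs (`.pstat` dialect): a header
#' row containing a parameter-name column and a `Mean` column, one row
#' per parameter.  Recognized parameter names (case-insensitive):
#' `clockrate...` for the mean clock rate, and either `m{1}`/`m{2}`/
#' `m{3}` (mapped to alpha1/alpha2/alpha3 in partition order) or
#' `rate_alpha1` etc. for the relative partition rates.  Unmatched
#' parameters are ignored with a message.
#'
#' @param path summary file.
#' @return a [clock_summary()].
#' @export
read_clock_summary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "[")]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty clock summary file: ", path)
  hdr_i <- grep("\\bMean\\b", lines, ignore.case = TRUE)[1]
  if (is.na(hdr_i)) stop("no 'Mean' column found in ", path)
  tab <- utils::read.table(text = lines[hdr_i:length(lines)], header = TRUE,
                           stringsAsFactors = FALSE, check.names = TRUE,
                           fill = TRUE)
  pname <- tab[[1]]
  mean_col <- grep("^mean$", names(tab), ignore.case = TRUE)[1]
  means <- as.numeric(tab[[mean_col]])

  is_clock <- grepl("^clockrate", pname, ignore.case = TRUE)
  if (!any(is_clock)) stop("no clockrate parameter found in ", path)
  m <- means[which(is_clock)[1]]

  rates <- c(alpha1 = NA_real_, alpha2 = NA_real_, alpha3 = NA_real_)
  idx <- regmatches(pname, regexec("^m\\{(\\d+)\\}", pname))
  for (k in seq_along(idx)) {
    if (length(idx[[k]]) == 2L) {
      p <- as.integer(idx[[k]][2])
      if (p >= 1L && p <= 3L) rates[p] <- means[k]
    }
  }
  named <- regmatches(pname, regexec("^rate_(alpha[123])$", pname,
                                     ignore.case = TRUE))
  for (k in seq_along(named)) {
    if (length(named[[k]]) == 2L)
      rates[tolower(named[[k]][2])] <- means[k]
  }
  rates <- rates[!is.na(rates)]
  if (!length(rates))
    stop("no relative partition rate parameters (m{i} or rate_alphai) in ",
         path)
  matched <- sum(is_clock) + length(rates)
  if (matched < length(pname))
    message(length(pname) - matched, " unrelated parameter(s) ignored")
  clock_summary(m, rates, source = path)
}

#' Per-chain substitution rates from a clock summary
#'
#' For each chain, the per-site rate is the mean clock rate times the
#' chain's relative partition rate (substitutions per site per Ma); the
#' whole-chain rate multiplies this by the chain length (substitutions
#' per Ma).  A mean row averages the three chains.  Values are exact
#' products; rounding happens only in the print method (half-up, one
#' decimal for the chain rate).
#'
#' @param summary a [clock_summary()].
#' @param lengths named chain lengths in sites (default: the canonical
#'   1058/1041/1062).
#' @return object of class `"chain_rate_table"`: data.frame with
#'   columns `chain`, `site_rate`, `length`, `chain_rate` and a final
#'   `mean` row.
#' @examples
#' cs <- clock_summary(0.00083, c(alpha1 = 0.00067 / 0.00083,
#'                                alpha2 = 0.00088 / 0.00083,
#'                                alpha3 = 0.00094 / 0.00083))
#' per_chain_rate(cs)
#' @export
per_chain_rate <- function(summary, lengths = CHAIN_LENGTHS) {
  stopifnot(inherits(summary, "clock_summary"))
  chains <- names(summary$relative_partition_rates)
  missing <- setdiff(chains, names(lengths))
  if (length(missing))
    stop("no length given for chain(s): ", paste(missing, collapse = ", "))
  site_rate <- summary$mean_clockrate * summary$relative_partition_rates
  len <- as.numeric(lengths[chains])
  chain_rate <- site_rate * len
  out <- data.frame(
    chain = c(chains, "mean"),
    site_rate = c(site_rate, mean(site_rate)),
    length = c(len, mean(len)),
    chain_rate = c(chain_rate, mean(chain_rate)),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("chain_rate_table", "data.frame")
  out
}

#' Display values of a chain rate table
#'
#' Applies the presentation rounding used for reporting: site rates to
#' five decimals, lengths to whole sites, whole-chain rates to one
#' decimal (half-up).
#'
#' @param x a `"chain_rate_table"`.
#' @return data.frame of formatted values.
#' @export
format_chain_rate_table <- function(x) {
  stopifnot(inherits(x, "chain_rate_table"))
  data.frame(
    chain = x$chain,
    site_rate = round_half_up(x$site_rate, 5),
    length = round_half_up(x$length, 0),
    chain_rate = round_half_up(x$chain_rate, 1),
    stringsAsFactors = FALSE)
}

#' @export
print.chain_rate_table <- function(x, ...) {
  cat("Per-chain substitution rates\n")
  f <- format_chain_rate_table(x)
  print.data.frame(
    data.frame(chain = f$chain,
               `subs/site/Ma` = sprintf("%.5f", f$site_rate),
               sites = sprintf("%d", as.integer(f$length)),
               `subs/chain/Ma` = sprintf("%.1f", f$chain_rate),
               check.names = FALSE),
    row.names = FALSE)
  invisible(x)
}
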