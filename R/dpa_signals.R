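# Vectorized signal cores. All take the four cell-count vectors and return
# a numeric vector; NA encodes an undefined signal (e.g. an empty drug row
# for PRR, a zero marginal for phi). Larger = stronger signal for every
# method. PRR and ROR use the Haldane-Anscombe correction (+0.5 to all four
# cells) when any of b, c, d is zero; the `corrected` flag records where it
# was applied.

pb_sig_freq <- function(a, b, c, d) as.numeric(a)

pb_sig_zero_correct <- function(a, b, c, d) {
  corr <- b == 0 | c == 0 | d == 0
  list(a = a + 0.5 * corr, b = b + 0.5 * corr, c = c + 0.5 * corr,
       d = d + 0.5 * corr, corrected = corr)
}

pb_sig_prr <- function(a, b, c, d) {
  undef <- (a + b) == 0
  z <- pb_sig_zero_correct(a, b, c, d)
  v <- (z$a / (z$a + z$b)) / (z$c / (z$c + z$d))
  v[undef] <- NA_real_
  list(value = v, corrected = z$corrected & !undef)
}

pb_sig_ror <- function(a, b, c, d) {
  z <- pb_sig_zero_correct(a, b, c, d)
  list(value = (z$a * z$d) / (z$b * z$c), corrected = z$corrected)
}

pb_sig_rrr <- function(a, b, c, d) {
  N <- a + b + c + d
  v <- ifelse(a == 0, 0, a * N / ((a + b) * (a + c)))
  as.numeric(v)
}

pb_sig_phi <- function(a, b, c, d) {
  m <- (a + b) * (c + d) * (a + c) * (b + d)
  ifelse(m > 0, (a * d - b * c) / sqrt(m), NA_real_)
}

pb_sig_ic <- function(a, b, c, d, mode = c("raw", "shrunk")) {
  mode <- match.arg(mode)
  N <- a + b + c + d
  if (mode == "raw") {
    ifelse(a > 0, log2(a * N / ((a + b) * (a + c))), NA_real_)
  } else {
    E <- ifelse(N > 0, (a + b) * (a + c) / N, NA_real_)
    log2((a + 0.5) / (E + 0.5))
  }
}

pb_cells <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  # doubles: marginal products overflow 32-bit integers at realistic N
  list(a = as.numeric(t$a), b = as.numeric(t$b), c = as.numeric(t$c), d = as.numeric(t$d))
}

#' Ranking signals on a 2x2 contingency table
#'
#' The disproportionality statistics used to rank drug--side-effect pairs,
#' each computed from the report-level 2x2 table (`a` drug & event, `b` drug
#' only, `c` event only, `d` neither):
#' \describe{
#'   \item{`freq`}{raw co-report count `a`.}
#'   \item{`prr`}{proportional reporting ratio
#'     `[a/(a+b)] / [c/(c+d)]`; `NA` (undefined) when the drug row is empty.}
#'   \item{`ror`}{reporting odds ratio `ad/bc`.}
#'   \item{`rrr`}{relative reporting ratio `aN/((a+b)(a+c))`, the observed
#'     over expected count under independence; 0 when `a = 0`.}
#'   \item{`phi_corr`}{phi coefficient
#'     `(ad - bc)/sqrt((a+b)(c+d)(a+c)(b+d))`, in `[-1, 1]`; `NA` when a
#'     marginal is zero.}
#'   \item{`ic`}{information component. `mode = "raw"` is
#'     `log2(aN/((a+b)(a+c)))`, identically `log2(rrr)`, undefined at
#'     `a = 0`; `mode = "shrunk"` is `log2((a+0.5)/(E+0.5))` with
#'     `E = (a+b)(a+c)/N`, finite for all tables.}
#' }
#' All three ratio measures equal 1 (and `phi_corr` 0, raw `ic` 0) under
#' independence `ad = bc`. `prr` and `ror` add 0.5 to all four cells when any
#' of `b`, `c`, `d` is zero (Haldane--Anscombe); the returned value then
#' carries attribute `corrected = TRUE`.
#'
#' @param t a [contingency_table()].
#' @param mode for `ic`: `"raw"` or `"shrunk"`.
#' @return a numeric scalar; `NA` marks an undefined signal.
#' @examples
#' t <- contingency_table(10, 90, 10, 890)
#' prr(t)  # 9
#' rrr(t)  # 5
#' ic(t)   # log2(5)
#' @name dpa-signals
NULL

#' @rdname dpa-signals
#' @export
freq <- function(t) { x <- pb_cells(t); pb_sig_freq(x$a, x$b, x$c, x$d) }

#' @rdname dpa-signals
#' @export
prr <- function(t) {
  x <- pb_cells(t); r <- pb_sig_prr(x$a, x$b, x$c, x$d)
  structure(r$value, corrected = r$corrected)
}

#' @rdname dpa-signals
#' @export
ror <- function(t) {
  x <- pb_cells(t); r <- pb_sig_ror(x$a, x$b, x$c, x$d)
  structure(r$value, corrected = r$corrected)
}

#' @rdname dpa-signals
#' @export
rrr <- function(t) { x <- pb_cells(t); pb_sig_rrr(x$a, x$b, x$c, x$d) }

#' @rdname dpa-signals
#' @export
phi_corr <- function(t) { x <- pb_cells(t); pb_sig_phi(x$a, x$b, x$c, x$d) }

#' @rdname dpa-signals
#' @export
ic <- function(t, mode = c("raw", "shrunk")) {
  x <- pb_cells(t); pb_sig_ic(x$a, x$b, x$c, x$d, mode)
}

#' Look up a pair's score in an external score table
#'
#' @param drug,se the pair.
#' @param ext an `external_scores` table (see [read_external_scores()]).
#' @return the score, or `NA` if the pair is absent from the table (absent
#'   pairs rank below all present pairs).
#' @export
external_signal <- function(drug, se, ext) {
  stopifnot(inherits(ext, "external_scores"))
  drug <- pb_normalize(drug); se <- pb_normalize(se)
  v <- ext$score[ext$drug == drug & ext$se == se]
  if (length(v)) v[1] else NA_real_
}

#' Score every extracted pair with one ranking method
#'
#' Applies one of the seven ranking signals to every pair in a `pair_counts`
#' object. `"external"` ranks by an external score table; extracted pairs
#' absent from the table get `NA` and sort below all present pairs.
#'
#' @param pc a `pair_counts` from [extract_pairs()].
#' @param method one of `"freq"`, `"prr"`, `"rrr"`, `"ror"`, `"phi"`,
#'   `"ic"`, `"external"`.
#' @param external an `external_scores` table, required for
#'   `method = "external"`.
#' @param ic_mode `"raw"` or `"shrunk"`, used for `method = "ic"`.
#' @return Object of class `signal_scores`: data.table with one row per pair,
#'   columns `drug`, `se`, `n` (co-report count, kept for tie-breaking),
#'   `method`, `value` (`NA` = undefined/absent), `corrected`.
#' @export
score_all <- function(pc, method = c("freq", "prr", "rrr", "ror", "phi", "ic", "external"),
                      external = NULL, ic_mode = c("raw", "shrunk")) {
  method <- tryCatch(match.arg(method),
                     error = function(e) pb_config_error(paste0("unknown method: '",
                                                                method[1], "'")))
  ic_mode <- match.arg(ic_mode)
  ct <- pb_contingency_all(pc)
  corrected <- rep(FALSE, nrow(ct))
  if (method == "external") {
    if (is.null(external)) pb_validation_error("method 'external' needs a score table")
    value <- external$score[match(pb_pair_key(ct$drug, ct$se),
                                  pb_pair_key(external$drug, external$se))]
  } else {
    value <- switch(method,
      freq = pb_sig_freq(ct$a, ct$b, ct$c, ct$d),
      prr = { r <- pb_sig_prr(ct$a, ct$b, ct$c, ct$d); corrected <- r$corrected; r$value },
      ror = { r <- pb_sig_ror(ct$a, ct$b, ct$c, ct$d); corrected <- r$corrected; r$value },
      rrr = pb_sig_rrr(ct$a, ct$b, ct$c, ct$d),
      phi = pb_sig_phi(ct$a, ct$b, ct$c, ct$d),
      ic = pb_sig_ic(ct$a, ct$b, ct$c, ct$d, ic_mode))
  }
  out <- data.table(drug = ct$drug, se = ct$se, n = ct$a, method = method,
                    value = as.numeric(value), corrected = corrected)
  setorder(out, drug, se)
  structure(out, class = c("signal_scores", class(out)))
}
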