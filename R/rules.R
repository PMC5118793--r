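#' Life-like transition rules
#'
#' A Life-like rule is written `B<digits>/S<digits>`: the birth set `B` lists
#' the alive-neighbour counts (0-8) that turn a dead cell alive, and the
#' survival set `S` those that keep an alive cell alive. On a network
#' tessellation the counts are mapped onto nine neighbourhood-density
#' intervals of width 1/9, so the same rule drives nodes of any degree.
#' There are `2^18 = 262144` distinct rules.
#'
#' @param x Rule text such as `"B3/S23"`. Case-insensitive; digits may appear
#'   in any order; either set may be empty (`"B/S"`).
#' @return An object of class `llna_rule`: a list with integer vectors
#'   `birth` and `survival` (ascending, within 0-8) and the normalized
#'   `name`.
#' @examples
#' llna_rule("B3/S23")
#' llna_rule("b135678/s03456")$name
#' @export
llna_rule <- function(x) {
  if (inherits(x, "llna_rule")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^[Bb]([0-8]*)/[Ss]([0-8]*)$", x))[[1]]
  if (length(m) == 0L) {
    bad <- sub("^[Bb][0-8]*", "", x)
    stop("malformed rule '", x, "': expected B<digits>/S<digits> with digits 0-8",
         if (nzchar(bad)) paste0(" (offending part: '", bad, "')"), call. = FALSE)
  }
  birth <- digits_of(m[2], x)
  survival <- digits_of(m[3], x)
  new_llna_rule(birth, survival)
}

digits_of <- function(s, orig) {
  if (!nzchar(s)) return(integer(0))
  d <- as.integer(strsplit(s, "")[[1]])
  if (anyDuplicated(d)) {
    stop("repeated digit '", d[duplicated(d)][1], "' in rule '", orig, "'",
         call. = FALSE)
  }
  sort(d)
}

new_llna_rule <- function(birth, survival) {
  structure(
    list(
      birth = as.integer(birth),
      survival = as.integer(survival),
      name = paste0("B", paste(birth, collapse = ""),
                    "/S", paste(survival, collapse = ""))
    ),
    class = "llna_rule"
  )
}

#' @export
print.llna_rule <- function(x, ...) {
  cat("<llna_rule> ", x$name, "\n", sep = "")
  invisible(x)
}

#' @export
format.llna_rule <- function(x, ...) x$name

#' Enumerate the Life-like rule space
#'
#' Every rule corresponds to an 18-bit mask: bit `i` (0-8) flags digit `i` in
#' the birth set, bit `i + 9` flags digit `i` in the survival set. Rules are
#' enumerated in ascending mask order, so `"B/S"` comes first and
#' `"B012345678/S012345678"` last. The mask is the canonical checkpointing
#' order for rule scans.
#'
#' @param ids Integer mask values in `0:(2^18 - 1)`. Defaults to the full
#'   rule space.
#' @return A character vector of canonical rule names, one per id.
#' @examples
#' enumerate_rules(0:3)
#' length(enumerate_rules()) # 262144
#' @export
enumerate_rules <- function(ids = 0:(2^18 - 1)) {
  stopifnot(all(ids >= 0), all(ids < 2^18))
  bits <- matrix(0L, nrow = length(ids), ncol = 18)
  rem <- as.integer(ids)
  for (b in 1:18) {
    bits[, b] <- rem %% 2L
    rem <- rem %/% 2L
  }
  digs <- as.character(0:8)
  b_part <- apply(bits[, 1:9, drop = FALSE], 1L,
                  function(r) paste(digs[r == 1L], collapse = ""))
  s_part <- apply(bits[, 10:18, drop = FALSE], 1L,
                  function(r) paste(digs[r == 1L], collapse = ""))
  paste0("B", b_part, "/S", s_part)
}

#' @rdname enumerate_rules
#' @param rule An `llna_rule` (or rule text).
#' @return `rule_id()`: the 18-bit integer mask of a rule.
#' @export
rule_id <- function(rule) {
  rule <- llna_rule(rule)
  sum(2^rule$birth) + sum(2^(rule$survival + 9))
}

#' Density-interval membership
#'
#' Digit `x` of a Life-like rule covers the density interval
#' `[x/9, (x+1)/9)`; the last digit's interval is closed, `[8/9, 1]`. The
#' nine intervals partition `[0, 1]`, so exactly one digit matches any
#' density.
#'
#' @param x Digit(s) in 0-8.
#' @param rho Neighbourhood density(ies) in `[0, 1]`. `x` and `rho` are
#'   recycled against each other.
#' @return Logical: is `rho` inside digit `x`'s interval?
#' @examples
#' interval_contains(3, 0.35)
#' interval_contains(8, 1)
#' @export
interval_contains <- function(x, rho) {
  stopifnot(all(x %in% 0:8))
  if (any(rho < 0 | rho > 1)) stop("density must lie in [0, 1]", call. = FALSE)
  n <- max(length(x), length(rho))
  x <- rep_len(as.integer(x), n)
  rho <- rep_len(rho, n)
  ifelse(x == 8L, rho >= 8 / 9 & rho <= 1, rho >= x / 9 & rho < (x + 1) / 9)
}

#' Birth and survival conditions of a rule
#'
#' A dead node is born when its neighbourhood density falls in the interval
#' of any digit of the birth set; an alive node survives when the density
#' falls in any survival digit's interval.
#'
#' @param rule An `llna_rule` or rule text.
#' @param rho Density value(s) in `[0, 1]`.
#' @return Logical vector along `rho`.
#' @examples
#' birth_satisfied("B3/S23", 0.35)
#' survival_satisfied("B3/S23", 0.30)
#' @export
birth_satisfied <- function(rule, rho) {
  set_satisfied(llna_rule(rule)$birth, rho)
}

#' @rdname birth_satisfied
#' @export
survival_satisfied <- function(rule, rho) {
  set_satisfied(llna_rule(rule)$survival, rho)
}

set_satisfied <- function(digits, rho) {
  if (length(digits) == 0L) {
    if (any(rho < 0 | rho > 1)) stop("density must lie in [0, 1]", call. = FALSE)
    return(rep(FALSE, length(rho)))
  }
  out <- rep(FALSE, length(rho))
  for (d in digits) out <- out | interval_contains(d, rho)
  out
}

# Interval lookup tables indexed by interval 0..8; used by the step kernels.
rule_tables <- function(rule) {
  rule <- llna_rule(rule)
  list(
    birth = 0:8 %in% rule$birth,
    survival = 0:8 %in% rule$survival
  )
}
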