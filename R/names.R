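#' Render and parse multi-field allele names
#'
#' A name is `<locus>*<f1>:<f2>:<f3>[:<f4>]`, e.g. `BF2*015:02:01`: the
#' first field is the allele-group number (zero-padded to three digits), the
#' second the nonsynonymous (protein) variant within the group, the third
#' the synonymous variant within the protein variant, and the fourth — only
#' rendered when non-coding data exist — the non-coding variant. Unlocated
#' class II B sequences use the bare locus token `BLB`.
#'
#' @param locus Gene name (`BLB1`, `BLB2`, `BF1`, `BF2`, or `BLB` for
#'   sequences without a clear genetic location).
#' @param f1,f2,f3 Integer fields (`f2`, `f3` default 1).
#' @param f4 Optional integer fourth field (`NA` = no non-coding data).
#' @return `render_allele_name()`: a canonical name string.
#' @export
render_allele_name <- function(locus, f1, f2 = 1L, f3 = 1L, f4 = NA_integer_) {
  base <- sprintf("%s*%03d:%02d:%02d", locus, f1, f2, f3)
  f4 <- rep_len(f4, length(base))
  out <- base
  out[!is.na(f4)] <- sprintf("%s:%02d", base[!is.na(f4)], f4[!is.na(f4)])
  out
}

#' @rdname render_allele_name
#' @param name A canonical allele name string.
#' @return `parse_allele_name()`: a tibble `locus`, `f1`, `f2`, `f3`, `f4`.
#' @export
parse_allele_name <- function(name) {
  m <- regexec("^([A-Za-z0-9]+)\\*([0-9]+)(?::([0-9]+))?(?::([0-9]+))?(?::([0-9]+))?$",
               name)
  parts <- regmatches(name, m)
  bad <- vapply(parts, length, integer(1)) == 0
  if (any(bad)) {
    abort(paste0("malformed allele name(s): ", paste(name[bad], collapse = ", ")))
  }
  g <- function(k, default) {
    v <- vapply(parts, `[`, character(1), k)
    ifelse(v == "", default, suppressWarnings(as.integer(v)))
  }
  tibble(locus = vapply(parts, `[`, character(1), 2),
         f1 = g(3, NA_integer_), f2 = g(4, 1L), f3 = g(5, 1L),
         f4 = g(6, NA_integer_))
}

#' Shorthand form of an allele name
#'
#' Trailing fields equal to the first-described variant (`01`) are dropped
#' and the leading zeros of the first field are stripped, so
#' `BF1*002:01:01` becomes `"2"` and `BF1*005:02:01` becomes `"5:02"`.
#'
#' @param name Canonical allele name string(s); the token `"null"` passes
#'   through unchanged.
#' @return Character vector of shorthand strings.
#' @export
allele_shorthand <- function(name) {
  vapply(name, function(nm) {
    if (is.na(nm) || nm %in% c("null", "?")) return(ifelse(is.na(nm), "?", nm))
    f <- parse_allele_name(nm)
    fields <- c(f$f2, f$f3, f$f4)
    fields <- fields[!is.na(fields)]
    while (length(fields) > 0 && tail(fields, 1) == 1L) {
      fields <- head(fields, -1L)
    }
    paste(c(as.character(f$f1), sprintf("%02d", fields)), collapse = ":")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a BF-BL haplotype record
#'
#' Slots hold canonical allele names, the token `"null"` (attested absence
#' of the gene, as for BF1 in some haplotypes), `"?"`/`NA` (unknown), or —
#' via `blb_pair` — a single unlocated class II B allele occupying both BLB
#' slots, rendered as a parenthesized pair such as `"(109-109)"`.
#'
#' @param haplotype Haplotype identifier (e.g. `"B19"`).
#' @param BLB1,BLB2,BF1,BF2 Slot values.
#' @param blb_pair Canonical name of an unlocated BLB allele filling both
#'   class II slots (overrides `BLB1`/`BLB2`).
#' @param provisional_suffix Optional letter distinguishing haplotypes that
#'   share a BF2 allele (e.g. the `b` of `Bfbl 6b`).
#' @return A `bfbl_haplotype` list.
#' @export
haplotype_record <- function(haplotype, BLB1 = NA, BLB2 = NA, BF1 = NA,
                             BF2 = NA, blb_pair = NA,
                             provisional_suffix = NA_character_) {
  structure(list(haplotype = haplotype,
                 slots = list(BLB1 = BLB1, BLB2 = BLB2, BF1 = BF1, BF2 = BF2),
                 blb_pair = blb_pair,
                 provisional_suffix = provisional_suffix),
            class = "bfbl_haplotype")
}

slot_token <- function(v, form) {
  if (length(v) != 1 || is.na(v) || v == "?") return("?")
  if (v == "null") return("null")
  if (form == "shorthand") allele_shorthand(v) else v
}

#' Render a haplotype as a string in BLB1-BLB2-BF1-BF2 order
#'
#' @param hap A `bfbl_haplotype`.
#' @param form `"shorthand"` (e.g. `"12-12:02-12:02-15:02"`) or
#'   `"canonical"` (full allele names).
#' @return A single string.
#' @export
haplotype_string <- function(hap, form = c("shorthand", "canonical")) {
  form <- match.arg(form)
  t3 <- slot_token(hap$slots$BF1, form)
  t4 <- slot_token(hap$slots$BF2, form)
  if (length(hap$blb_pair) == 1 && !is.na(hap$blb_pair)) {
    p <- slot_token(hap$blb_pair, form)
    paste(c(sprintf("(%s-%s)", p, p), t3, t4), collapse = "-")
  } else {
    paste(c(slot_token(hap$slots$BLB1, form), slot_token(hap$slots$BLB2, form),
            t3, t4), collapse = "-")
  }
}

#' Bfbl haplotype name
#'
#' BF-BL haplotypes are named after their BF2 allele shorthand (a Bfbl
#' haplotype, distinct from the whole-B-locus haplotype), with a provisional
#' letter suffix when a distinct background shares that BF2 allele.
#'
#' @param hap A `bfbl_haplotype`.
#' @return A single string, `NA` when the BF2 slot is unknown.
#' @export
bfbl_name <- function(hap) {
  t <- slot_token(hap$slots$BF2, "shorthand")
  if (t %in% c("?", "null")) return(NA_character_)
  suffix <- hap$provisional_suffix
  paste0(t, if (!is.na(suffix)) suffix else "")
}

#' Parse a haplotype string back into slot tokens
#'
#' Inverse of [haplotype_string()] at the token level. Handles the `null`
#' and `?` tokens and the parenthesized ambiguous-BLB pair.
#'
#' @param x A haplotype string.
#' @return A list with `blb_pair` (shorthand or `NA`) and `tokens`, a named
#'   character vector of the four slot tokens.
#' @export
parse_haplotype_string <- function(x) {
  pair <- NA_character_
  if (startsWith(x, "(")) {
    m <- regexec("^\\(([^-]+)-([^)]+)\\)-(.+)$", x)[[1]]
    parts <- regmatches(x, list(m))[[1]]
    if (length(parts) == 0 || parts[2] != parts[3]) {
      abort(paste0("malformed ambiguous-BLB pair in haplotype string: ", x))
    }
    pair <- parts[2]
    rest <- strsplit(parts[4], "-", fixed = TRUE)[[1]]
    if (length(rest) != 2) abort(paste0("expected two BF tokens in: ", x))
    tokens <- c(BLB1 = pair, BLB2 = pair, BF1 = rest[1], BF2 = rest[2])
  } else {
    toks <- strsplit(x, "-", fixed = TRUE)[[1]]
    if (length(toks) != 4) abort(paste0("expected four tokens in: ", x))
    tokens <- setNames(toks, c("BLB1", "BLB2", "BF1", "BF2"))
  }
  list(blb_pair = pair, tokens = tokens)
}

#' Parse an old-style recombinant haplotype name
#'
#' Names like `B2r1` (the first described recombinant carrying the BF2
#' allele of the B2 haplotype) are accepted for backward compatibility but
#' never emitted.
#'
#' @param x Strings like `"B2r1"`.
#' @return A tibble `bf2_group`, `r_index`.
#' @export
parse_legacy_recombinant <- function(x) {
  m <- regexec("^B([0-9]+)r([0-9]+)$", x)
  parts <- regmatches(x, m)
  bad <- vapply(parts, length, integer(1)) == 0
  if (any(bad)) {
    abort(paste0("not an old-style recombinant name: ",
                 paste(x[bad], collapse = ", ")))
  }
  tibble(bf2_group = as.integer(vapply(parts, `[`, character(1), 2)),
         r_index = as.integer(vapply(parts, `[`, character(1), 3)))
}
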