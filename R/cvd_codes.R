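# Cardiovascular-death endpoint coding.

# The 57 cause-of-death codes defining the cardiovascular mortality endpoint
# (I-chapter codes as printed in the source registry extract).
CVD_DEATH_CODES <- c(
  "I10", "I38", "I48", "I64",
  "I110", "I119", "I120", "I132",
  "I210", "I211", "I219",
  "I248", "I249", "I250", "I251", "I255", "I259",
  "I269", "I272", "I279", "I288",
  "I348", "I350", "I359",
  "I420", "I422", "I429", "I442", "I449",
  "I461", "I469", "I490", "I499",
  "I500", "I509", "I516", "I519",
  "I609", "I619", "I629", "I630", "I633", "I639",
  "I652", "I671", "I679",
  "I709", "I710", "I711", "I712", "I713", "I714", "I719",
  "I720", "I739", "I740", "I770")

#' Is a cause-of-death code a cardiovascular death?
#'
#' The code is upper-cased and stripped of dots before membership lookup in
#' the fixed 57-code cardiovascular list (e.g. `"i25.0"` matches `"I250"`).
#' Unknown or non-listed codes return `FALSE`.
#'
#' @param code a non-empty alphanumeric code (dots allowed).
#' @return logical scalar.
#' @export
is_cvd_death_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || !nzchar(code))
    stop("`code` must be a non-empty string")
  gsub(".", "", toupper(code), fixed = TRUE) %in% CVD_DEATH_CODES
}
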