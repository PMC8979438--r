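# Shared constants and small internal helpers.

#' Standard amino-acid alphabet
#'
#' The 20 one-letter amino-acid codes in alphabetical order. Gap characters
#' are normalized to \code{"-"} throughout the package and, where they enter
#' a calculation at all (mutual information), are treated as a 21st type.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Closed phenotype vocabulary
#'
#' Variant phenotype labels form a closed set: anything else is a parsing
#' error, never a fourth class.
#'
#' @format Character vector of length 3.
#' @export
PHENOTYPE_LEVELS <- c("control", "mild", "severe")

#' Registered feature-column vocabulary
#'
#' The 14 named molecular signatures a \linkS4class{FeatureTable} may carry:
#' sequence (S_i, MI_mean, conservation), structure (RASA), stability (ddG),
#' contact-network deltas (dDC, dBC, dCC, dC) and elastic-network dynamics
#' (MSF, effectiveness, sensitivity, MBS, stiffness).
#'
#' @format Character vector of length 14.
#' @export
FEATURE_VOCABULARY <- c("S_i", "MI_mean", "conservation", "RASA", "ddG",
                        "dDC", "dBC", "dCC", "dC",
                        "MSF", "effectiveness", "sensitivity", "MBS",
                        "stiffness")

# one- <-> three-letter residue code tables
.AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.AA_123 <- structure(names(.AA_321), names = unname(.AA_321))

aa321 <- function(three) unname(.AA_321[toupper(three)])
aa123 <- function(one) unname(.AA_123[toupper(one)])

# residue key "chain:position" used wherever mutations index structures
residueKey <- function(chain, position) paste(chain, position, sep = ":")

# deterministic seed streams: derive a child seed < 2^31 from a parent seed
# and a stream tag, so independent generators never share a stream
childSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483399) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
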