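# Internal helpers shared across modules.

# Classed error so callers can test on condition class rather than message text.
abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "nbrank_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Residue identity key used to match residues across poses of the same complex:
# author chain id + residue number + insertion code.
res_key <- function(chain, resno, ins) {
  ins <- ifelse(is.na(ins) | ins == " ", "", ins)
  paste0(chain, ":", resno, ins)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
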