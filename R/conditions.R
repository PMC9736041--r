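# Classed error conditions so callers (and tests) can distinguish failure
# modes of parsing/validation without matching on message text.

.dvhError <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "dvhError", "error", "condition"),
    list(message = msg, call = call)
  ))
}

.errMalformedHeader <- function(msg) .dvhError("dvhMalformedHeader", msg)
.errNonMonotone <- function(msg) .dvhError("dvhNonMonotone", msg)
.errNegativeVolume <- function(msg) .dvhError("dvhNegativeVolume", msg)
.errMissingMetadata <- function(msg) .dvhError("dvhMissingMetadata", msg)
.errWrongKind <- function(msg) .dvhError("dvhWrongKind", msg)
.errBadArgument <- function(msg) .dvhError("dvhBadArgument", msg)
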