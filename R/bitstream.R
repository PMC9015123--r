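# Bit-level serialisation primitives.
#
# The archive body is a single MSB-first bitstream. Fields are either
# fixed-width unsigned integers or varints (LEB128-style: 8-bit groups, 7
# payload bits each, high bit = continuation). Writers accumulate parallel
# (value, width) vectors and pack once at the end, which keeps everything
# vectorised.

# value/width pair lists ----------------------------------------------------

bf <- function(values, widths) list(values = as.numeric(values),
                                    widths = as.integer(widths))

bf_concat <- function(parts) {
  list(values = unlist(lapply(parts, `[[`, "values"), use.names = FALSE),
       widths = unlist(lapply(parts, `[[`, "widths"), use.names = FALSE))
}

bf_nbits <- function(f) sum(f$widths)

# MSB-first packing of mixed-width unsigned fields into bytes.
pack_bit_fields <- function(f) {
  values <- f$values
  widths <- f$widths
  if (!length(values)) return(raw(0))
  idx <- rep.int(seq_along(values), widths)
  exps <- sequence(widths, from = widths - 1L, by = -1L)
  bits <- (values[idx] %/% 2^exps) %% 2
  pad <- (-length(bits)) %% 8L
  if (pad) bits <- c(bits, numeric(pad))
  as.raw(as.integer(crossprod(2^(7:0), matrix(bits, nrow = 8L))))
}

# reader --------------------------------------------------------------------

bit_reader <- function(r) {
  m <- matrix(as.integer(rawToBits(r)), nrow = 8L)
  env <- new.env(parent = emptyenv())
  env$bits <- as.vector(m[8:1, , drop = FALSE])
  env$pos <- 0L
  env
}

read_uint <- function(br, width, n = 1L) {
  need <- as.integer(width * n)
  if (br$pos + need > length(br$bits)) stop_format("corrupt archive: truncated payload")
  b <- br$bits[br$pos + seq_len(need)]
  br$pos <- br$pos + need
  if (n == 1L) {
    sum(b * 2^((width - 1L):0))
  } else {
    as.vector(crossprod(matrix(b, nrow = width), 2^((width - 1L):0)))
  }
}

# varints -------------------------------------------------------------------

varint_fields <- function(v) {
  stopifnot(v >= 0)
  vals <- numeric(0)
  repeat {
    g <- v %% 128
    v <- v %/% 128
    if (v > 0) vals <- c(vals, g + 128) else { vals <- c(vals, g); break }
  }
  bf(vals, rep(8L, length(vals)))
}

read_varint <- function(br) {
  v <- 0
  mult <- 1
  repeat {
    g <- read_uint(br, 8L)
    v <- v + (g %% 128) * mult
    if (g < 128) return(v)
    mult <- mult * 128
  }
}

# Serialized size of a varint, in bits; vectorised.
varint_nbits <- function(v) {
  nb <- floor(log2(pmax(v, 1))) + 1
  8 * pmax(1, ceiling(nb / 7))
}
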