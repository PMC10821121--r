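# Shared miniature fixtures built in code.

# A hand-sized triad: donor has {a,b,c,d}, pre has {a,e}, post has {a,b,f}.
tiny_triad_counts <- function() {
  m <- matrix(0L, nrow = 3, ncol = 6,
              dimnames = list(c("D1", "pre1", "post1"),
                              c("a", "b", "c", "d", "e", "f")))
  m["D1", c("a", "b", "c", "d")] <- c(10L, 20L, 30L, 40L)
  m["pre1", c("a", "e")] <- c(5L, 15L)
  m["post1", c("a", "b", "f")] <- c(8L, 12L, 4L)
  m
}

tiny_triad <- function() {
  data.frame(recipient_id = "dog1", donor_id = "donorA",
             donor_sample = "D1", pre_sample = "pre1", post_sample = "post1",
             stringsAsFactors = FALSE)
}

tiny_metadata <- function() {
  data.frame(
    sample_id = c("D1", "pre1", "post1"),
    dog_id = c("donorA", "dog1", "dog1"),
    role = c("donor", "preFMT", "postFMT"),
    donor_id = c(NA, "donorA", "donorA"),
    stringsAsFactors = FALSE)
}
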