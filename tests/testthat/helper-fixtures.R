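# Shared fixtures: small host/phage pairs carrying the 17-bp att core, and
# a full-scale pair (65,149 bp phage, core in reverse orientation at
# 62,750, pac at 23,500) for parameter-recovery tests.

ATT_CORE <- "TGGTGCGGACGGAGAGA"

# small trio for unit tests: fast to index and classify
makeSmallTrio <- function(seed = 11, hostLen = 2e5, phageLen = 2e4,
                          attB = 150000L, attP = 15000L,
                          orientation = "reverse") {
    host <- plantAttCore(randomGenome(hostLen, 0.66, seed = seed,
                                      name = "host"),
                         ATT_CORE, attB)
    phage <- plantAttCore(randomGenome(phageLen, 0.635, seed = seed + 1,
                                       name = "phage"),
                          ATT_CORE, attP,
                          reverse = orientation == "reverse")
    att <- attSite(ATT_CORE, attB, attP, orientation)
    list(host = host, phage = phage, att = att)
}

# full-scale phage geometry (65,149 bp, reverse-orientation core at 62,750)
# on a compact 2-Mb host
makeFullScaleTrio <- function(seed = 21, hostLen = 2e6, attB = 1600000L) {
    host <- plantAttCore(randomGenome(hostLen, 0.665, seed = seed,
                                      name = "host"),
                         ATT_CORE, attB)
    phage <- plantAttCore(randomGenome(65149, 0.635, seed = seed + 1,
                                       name = "phage"),
                          ATT_CORE, 62750L, reverse = TRUE)
    att <- attSite(ATT_CORE, attB, 62750L, "reverse")
    list(host = host, phage = phage, att = att)
}

# one truth row per read (first segment carries the class/anchors)
truthPerRead <- function(reads) {
    tr <- readTruth(reads)
    tr[!duplicated(tr$readId),
       c("readId", "truthClass", "hostAnchor", "phageAnchor")]
}
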