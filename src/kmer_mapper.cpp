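// Exact k-mer seed mapper used by the read classifier.
//
// The index stores every canonical k-mer of each reference (both strands are
// represented by the lexicographically smaller of a k-mer and its reverse
// complement) in a sorted array, so lookups are binary searches.  Reads are
// seeded at a fixed stride, seeds are grouped by (reference, strand,
// diagonal), and each candidate ungapped placement is verified base-by-base.
// The reported alignment is the longest contiguous match run, chained across
// isolated single mismatches so low-rate substitution errors do not truncate
// it.  Circular references wrap both during indexing and verification.

#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <map>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int baseCode(char b) {
    switch (b) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    }
    return 4;
}

static inline char compBase(char b) {
    switch (b) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    }
    return 'N';
}

struct KmerIndexCpp {
    int k;
    std::vector<std::string> seqs;
    std::vector<bool> circular;
    // parallel arrays sorted by key; val packs ref (8 bits, <<41),
    // canonical-is-forward flag (<<40) and position (40 bits)
    std::vector<uint64_t> keys;
    std::vector<uint64_t> vals;
};

static void collectKmers(const std::string& s, bool circ, int k, int refId,
                         std::vector<std::pair<uint64_t, uint64_t> >& out) {
    const long L = (long)s.size();
    if (L < k) return;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    const int shift = 2 * (k - 1);
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    const long nPos = circ ? L : (L - k + 1);
    const long nIter = circ ? (L + k - 1) : L;
    for (long i = 0; i < nIter; ++i) {
        int c = baseCode(s[i % L]);
        if (c > 3) { valid = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)c) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
        if (++valid < k) continue;
        long pos = i - k + 1;           // start position (mod L for circular)
        if (pos >= nPos) break;
        if (pos < 0) continue;
        bool fwdCanon = fwd <= rev;
        uint64_t key = fwdCanon ? fwd : rev;
        uint64_t val = ((uint64_t)refId << 41) |
                       ((uint64_t)(fwdCanon ? 1 : 0) << 40) |
                       (uint64_t)(pos % L);
        out.push_back(std::make_pair(key, val));
    }
}

// [[Rcpp::export(name = ".kmerIndexBuild")]]
SEXP kmerIndexBuild(CharacterVector seqs, LogicalVector circ, int k) {
    if (k < 2 || k > 32) stop("k must be in [2, 32]");
    KmerIndexCpp* idx = new KmerIndexCpp();
    idx->k = k;
    std::vector<std::pair<uint64_t, uint64_t> > entries;
    for (int r = 0; r < seqs.size(); ++r) {
        idx->seqs.push_back(as<std::string>(seqs[r]));
        idx->circular.push_back(circ[r] == TRUE);
        collectKmers(idx->seqs.back(), idx->circular.back(), k, r, entries);
    }
    std::sort(entries.begin(), entries.end());
    idx->keys.reserve(entries.size());
    idx->vals.reserve(entries.size());
    for (size_t i = 0; i < entries.size(); ++i) {
        idx->keys.push_back(entries[i].first);
        idx->vals.push_back(entries[i].second);
    }
    XPtr<KmerIndexCpp> p(idx, true);
    return p;
}

static bool encodeKmer(const char* s, int k, uint64_t& fwd, uint64_t& rev) {
    const int shift = 2 * (k - 1);
    fwd = 0; rev = 0;
    for (int i = 0; i < k; ++i) {
        int c = baseCode(s[i]);
        if (c > 3) return false;
        fwd = (fwd << 2) | (uint64_t)c;
        rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    }
    return true;
}

// [[Rcpp::export(name = ".kmerIndexQuery")]]
DataFrame kmerIndexQuery(SEXP xp, CharacterVector kmers) {
    XPtr<KmerIndexCpp> idx(xp);
    std::vector<int> qIdx, refIdx;
    std::vector<long> pos;
    std::vector<std::string> strand;
    for (int q = 0; q < kmers.size(); ++q) {
        std::string s = as<std::string>(kmers[q]);
        if ((int)s.size() != idx->k) stop("query length must equal k");
        uint64_t fwd, rev;
        if (!encodeKmer(s.c_str(), idx->k, fwd, rev)) continue;
        bool queryFwdCanon = fwd <= rev;
        uint64_t key = queryFwdCanon ? fwd : rev;
        std::vector<uint64_t>::const_iterator lo =
            std::lower_bound(idx->keys.begin(), idx->keys.end(), key);
        for (; lo != idx->keys.end() && *lo == key; ++lo) {
            uint64_t val = idx->vals[lo - idx->keys.begin()];
            bool refFwdCanon = (val >> 40) & 1ULL;
            qIdx.push_back(q + 1);
            refIdx.push_back((int)(val >> 41) + 1);
            pos.push_back((long)(val & ((1ULL << 40) - 1)));
            strand.push_back(queryFwdCanon == refFwdCanon ? "+" : "-");
        }
    }
    return DataFrame::create(_["query"] = qIdx, _["ref"] = refIdx,
                             _["pos"] = pos, _["strand"] = strand,
                             _["stringsAsFactors"] = false);
}

struct Placement {
    int ref;
    bool fwd;        // read aligns forward (true) or reverse-complemented
    long offset;     // ref position of (oriented) read base 0, may be negative
    int nseeds;
};

// verify an ungapped placement and extract the best match run
struct RunResult {
    int matched, readStart, readEnd;  // oriented read coords, half-open
    long refStart;                    // ref coord of readStart (mod L)
};

static bool verifyPlacement(const std::string& ref, bool circ, long L,
                            const std::string& read, long offset,
                            RunResult& out) {
    const int n = (int)read.size();
    std::vector<signed char> m(n, -1);  // 1 match, 0 mismatch, -1 off-reference
    for (int i = 0; i < n; ++i) {
        long p = offset + i;
        if (circ) p = ((p % L) + L) % L;
        else if (p < 0 || p >= L) continue;
        m[i] = (baseCode(read[i]) <= 3 && ref[p] == read[i]) ? 1 : 0;
    }
    // contiguous match runs
    std::vector<int> rs, re;  // [rs, re)
    int i = 0;
    while (i < n) {
        if (m[i] == 1) {
            int j = i;
            while (j < n && m[j] == 1) ++j;
            rs.push_back(i); re.push_back(j);
            i = j;
        } else ++i;
    }
    if (rs.empty()) return false;
    // chain from the longest run across isolated single mismatches when the
    // neighbouring run is long enough not to be a chance match
    int best = 0;
    for (size_t r = 1; r < rs.size(); ++r)
        if (re[r] - rs[r] > re[best] - rs[best]) best = (int)r;
    int lo = best, hi = best;
    while (lo > 0 && rs[lo] - re[lo - 1] == 1 && re[lo - 1] - rs[lo - 1] >= 4) --lo;
    while (hi + 1 < (int)rs.size() && rs[hi + 1] - re[hi] == 1 &&
           re[hi + 1] - rs[hi + 1] >= 4) ++hi;
    int matched = 0;
    for (int r = lo; r <= hi; ++r) matched += re[r] - rs[r];
    out.matched = matched;
    out.readStart = rs[lo];
    out.readEnd = re[hi];
    long p = offset + rs[lo];
    if (circ) p = ((p % L) + L) % L;
    out.refStart = p;
    return true;
}

// [[Rcpp::export(name = ".mapReadsCpp")]]
DataFrame mapReadsCpp(SEXP xp, CharacterVector reads, int stride,
                      int maxPlacements) {
    XPtr<KmerIndexCpp> idx(xp);
    const int k = idx->k;
    std::vector<int> oRead, oRef, oMatched, oReadStart, oReadEnd, oSeeds;
    std::vector<long> oRefStart, oRefEnd;
    std::vector<std::string> oStrand;

    for (int q = 0; q < reads.size(); ++q) {
        std::string rd = as<std::string>(reads[q]);
        const int n = (int)rd.size();
        if (n < k) continue;
        std::string rc(n, 'N');
        for (int i = 0; i < n; ++i) rc[n - 1 - i] = compBase(rd[i]);

        // seed positions: fixed stride plus the final k-mer
        std::map<std::pair<int, std::pair<int, long> >, int> groups;
        std::vector<int> seedPos;
        for (int s = 0; s <= n - k; s += stride) seedPos.push_back(s);
        if (seedPos.back() != n - k) seedPos.push_back(n - k);
        for (size_t si = 0; si < seedPos.size(); ++si) {
            int s = seedPos[si];
            uint64_t fwd, rev;
            if (!encodeKmer(rd.c_str() + s, k, fwd, rev)) continue;
            bool readFwdCanon = fwd <= rev;
            uint64_t key = readFwdCanon ? fwd : rev;
            std::vector<uint64_t>::const_iterator lo =
                std::lower_bound(idx->keys.begin(), idx->keys.end(), key);
            for (; lo != idx->keys.end() && *lo == key; ++lo) {
                uint64_t val = idx->vals[lo - idx->keys.begin()];
                bool refFwdCanon = (val >> 40) & 1ULL;
                int ref = (int)(val >> 41);
                long pos = (long)(val & ((1ULL << 40) - 1));
                bool sameStrand = (readFwdCanon == refFwdCanon);
                long L = (long)idx->seqs[ref].size();
                long offset;   // ref pos of oriented read base 0
                if (sameStrand) offset = pos - s;
                else offset = pos - (long)(n - s - k);   // rc(read) base 0
                long key2 = offset;
                if (idx->circular[ref]) key2 = ((offset % L) + L) % L;
                groups[std::make_pair(ref,
                    std::make_pair(sameStrand ? 1 : 0, key2))]++;
            }
        }
        if (groups.empty()) continue;
        // rank groups by seed support
        std::vector<std::pair<int, std::pair<int, std::pair<int, long> > > > gv;
        for (std::map<std::pair<int, std::pair<int, long> >, int>::iterator it =
                 groups.begin(); it != groups.end(); ++it)
            gv.push_back(std::make_pair(it->second,
                std::make_pair(it->first.first, it->first.second)));
        std::sort(gv.rbegin(), gv.rend());
        int nEval = std::min((int)gv.size(), maxPlacements);
        for (int g = 0; g < nEval; ++g) {
            int ref = gv[g].second.first;
            bool fwdStrand = gv[g].second.second.first == 1;
            long offset = gv[g].second.second.second;
            long L = (long)idx->seqs[ref].size();
            const std::string& oriented = fwdStrand ? rd : rc;
            RunResult rr;
            if (!verifyPlacement(idx->seqs[ref], idx->circular[ref], L,
                                 oriented, offset, rr)) continue;
            if (rr.matched < k) continue;
            // convert oriented read coords back to original read coords
            int readStart = fwdStrand ? rr.readStart : n - rr.readEnd;
            int readEnd = fwdStrand ? rr.readEnd : n - rr.readStart;
            oRead.push_back(q + 1);
            oRef.push_back(ref + 1);
            oStrand.push_back(fwdStrand ? "+" : "-");
            oRefStart.push_back(rr.refStart);
            oRefEnd.push_back(rr.refStart + (rr.readEnd - rr.readStart));
            oReadStart.push_back(readStart);
            oReadEnd.push_back(readEnd);
            oMatched.push_back(rr.matched);
            oSeeds.push_back(gv[g].first);
        }
    }
    return DataFrame::create(
        _["read"] = oRead, _["ref"] = oRef, _["strand"] = oStrand,
        _["ref_start"] = oRefStart, _["ref_end"] = oRefEnd,
        _["read_start"] = oReadStart, _["read_end"] = oReadEnd,
        _["matched"] = oMatched, _["nseeds"] = oSeeds,
        _["stringsAsFactors"] = false);
}
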