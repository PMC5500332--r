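#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>

using namespace Rcpp;

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default:  return 'N';
    }
}

static std::string revcomp_one(const std::string &s) {
    std::string out(s.rbegin(), s.rend());
    for (size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
    return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (CharacterVector::is_na(seqs[i])) { out[i] = NA_STRING; continue; }
        out[i] = revcomp_one(as<std::string>(seqs[i]));
    }
    return out;
}

// Per-base substitution with probability error_rate; substitutes to one of
// the three other bases uniformly. Uses R's RNG so set.seed() governs it.
// [[Rcpp::export(name = ".mutate_seqs_cpp")]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double error_rate) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    if (error_rate <= 0.0) return clone(seqs);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        for (size_t j = 0; j < s.size(); ++j) {
            if (unif_rand() < error_rate) {
                char cur = s[j];
                char sub;
                do {
                    sub = bases[(int)(unif_rand() * 4.0) & 3];
                } while (sub == cur);
                s[j] = sub;
            }
        }
        out[i] = s;
    }
    return out;
}

// Merge forward read with the reverse complement of the reverse read.
// Finds the LARGEST overlap o (min_overlap <= o <= min(len)) where a suffix
// of fwd aligns to a prefix of rc(rev) at >= min_identity; mismatches in the
// overlap resolved in favour of the forward read.
// [[Rcpp::export(name = ".join_pairs_cpp")]]
List join_pairs_cpp(CharacterVector fwd, CharacterVector rev,
                    int min_overlap, double min_identity) {
    R_xlen_t n = fwd.size();
    if (rev.size() != n) stop("forward and reverse vectors differ in length");
    CharacterVector contig(n);
    LogicalVector joined(n);
    IntegerVector overlap_len(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string f = as<std::string>(fwd[i]);
        std::string r = revcomp_one(as<std::string>(rev[i]));
        int lf = (int)f.size(), lr = (int)r.size();
        int omax = lf < lr ? lf : lr;
        int best = -1;
        for (int o = omax; o >= min_overlap; --o) {
            int mism = 0;
            int allowed = (int)std::floor((1.0 - min_identity) * o + 1e-9);
            const char *pf = f.data() + (lf - o);
            const char *pr = r.data();
            bool ok = true;
            for (int j = 0; j < o; ++j) {
                if (pf[j] != pr[j]) {
                    if (++mism > allowed) { ok = false; break; }
                }
            }
            if (ok) { best = o; break; }
        }
        if (best < 0) {
            contig[i] = NA_STRING;
            joined[i] = false;
            overlap_len[i] = 0;
        } else {
            // forward read wins inside the overlap
            std::string merged = f + r.substr(best);
            contig[i] = merged;
            joined[i] = true;
            overlap_len[i] = best;
        }
    }
    return List::create(_["contig"] = contig, _["joined"] = joined,
                        _["overlap"] = overlap_len);
}

struct KmerIndex {
    std::unordered_map<std::string, std::vector<int>> map; // kmer -> ref ids
    std::vector<std::string> refs;
    int k;
};

static void index_seq(KmerIndex &idx, const std::string &s, int id) {
    if ((int)s.size() < idx.k) return;
    for (size_t p = 0; p + idx.k <= s.size(); ++p) {
        std::string km = s.substr(p, idx.k);
        std::vector<int> &v = idx.map[km];
        if (v.empty() || v.back() != id) v.push_back(id);
    }
}

// Best ungapped sliding alignment of q against ref (one orientation).
// Considers every offset; alignment columns = length of the overlapped
// region at that offset. Returns best (identity, length) subject to
// length >= min_len, preferring higher identity then longer alignment.
static bool slide_best(const std::string &q, const std::string &ref,
                       int min_len, double &best_ident, int &best_len) {
    int lq = (int)q.size(), lr = (int)ref.size();
    bool found = false;
    for (int off = -(lq - min_len); off <= lr - min_len; ++off) {
        int qs = off < 0 ? -off : 0;
        int rs = off > 0 ? off : 0;
        int len = std::min(lq - qs, lr - rs);
        if (len < min_len) continue;
        int match = 0;
        const char *pq = q.data() + qs;
        const char *pr = ref.data() + rs;
        for (int j = 0; j < len; ++j)
            if (pq[j] == pr[j]) ++match;
        double ident = (double)match / (double)len;
        if (!found || ident > best_ident ||
            (ident == best_ident && len > best_len)) {
            best_ident = ident;
            best_len = len;
            found = true;
        }
    }
    return found;
}

// For each query: retrieve candidate references sharing >= 1 k-mer (both
// orientations when check_rc), then verify by ungapped sliding alignment.
// Returns, per query, the best reference index (1-based, 0 = none), its
// identity and alignment length, and whether it clears (identity >=
// min_identity AND length >= min_len).
// [[Rcpp::export(name = ".kmer_match_cpp")]]
List kmer_match_cpp(CharacterVector queries, CharacterVector refs,
                    int k, int min_len, double min_identity,
                    bool check_rc, bool first_hit_exit) {
    KmerIndex idx;
    idx.k = k;
    int nref = refs.size();
    idx.refs.reserve(nref);
    for (int i = 0; i < nref; ++i) {
        std::string s = as<std::string>(refs[i]);
        idx.refs.push_back(s);
        index_seq(idx, s, i);
    }
    R_xlen_t nq = queries.size();
    IntegerVector best_ref(nq, 0);
    NumericVector best_ident(nq, NA_REAL);
    IntegerVector best_len(nq, 0);
    LogicalVector matched(nq, false);
    std::vector<int> seen(nref, -1);
    for (R_xlen_t i = 0; i < nq; ++i) {
        std::string q = as<std::string>(queries[i]);
        std::string qrc = check_rc ? revcomp_one(q) : std::string();
        double bi = -1.0;
        int bl = 0, br = 0;
        bool hit = false;
        for (int orient = 0; orient < (check_rc ? 2 : 1); ++orient) {
            const std::string &qq = orient == 0 ? q : qrc;
            if ((int)qq.size() < k) continue;
            for (size_t p = 0; p + k <= qq.size(); ++p) {
                auto it = idx.map.find(qq.substr(p, k));
                if (it == idx.map.end()) continue;
                for (int rid : it->second) {
                    if (seen[rid] == (int)i * 2 + orient) continue;
                    seen[rid] = (int)i * 2 + orient;
                    double ident = -1.0;
                    int len = 0;
                    if (slide_best(qq, idx.refs[rid], min_len, ident, len)) {
                        if (ident > bi || (ident == bi && len > bl)) {
                            bi = ident;
                            bl = len;
                            br = rid + 1;
                        }
                        if (ident >= min_identity && len >= min_len) {
                            hit = true;
                        }
                    }
                }
                if (hit && first_hit_exit) break;
            }
            if (hit && first_hit_exit) break;
        }
        if (br > 0) {
            best_ref[i] = br;
            best_ident[i] = bi;
            best_len[i] = bl;
            matched[i] = hit || (bi >= min_identity && bl >= min_len);
        }
    }
    return List::create(_["ref"] = best_ref, _["identity"] = best_ident,
                        _["length"] = best_len, _["matched"] = matched);
}

// Hamming identity between equal-length strings (fraction of matching
// positions); used by the reference-set collision check.
// [[Rcpp::export(name = ".pairwise_identity_cpp")]]
NumericMatrix pairwise_identity_cpp(CharacterVector seqs) {
    int n = seqs.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
    NumericMatrix out(n, n);
    for (int i = 0; i < n; ++i) {
        out(i, i) = 1.0;
        for (int j = i + 1; j < n; ++j) {
            if (s[i].size() != s[j].size())
                stop("sequences must have equal length");
            int match = 0;
            for (size_t p = 0; p < s[i].size(); ++p)
                if (s[i][p] == s[j][p]) ++match;
            double ident = (double)match / (double)s[i].size();
            out(i, j) = ident;
            out(j, i) = ident;
        }
    }
    return out;
}
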