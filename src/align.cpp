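// Affine-gap local/global alignment core, six-frame translated screening,
// and ungapped sliding overlaps for the greedy assembler.
//
// Gap model throughout: a gap of length L costs gap_open + (L-1) * gap_extend
// (the opening charge is levied on the first gap residue).

#include <Rcpp.h>
#include <cstring>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const int NEG_INF = INT_MIN / 4;

struct Alpha {
    int map[256];
    int n;
    Alpha(const std::string &alphabet) {
        n = (int)alphabet.size();
        for (int i = 0; i < 256; ++i) map[i] = -1;
        for (int i = 0; i < n; ++i) map[(unsigned char)alphabet[i]] = i;
    }
    inline int idx(char c, const char *what) const {
        int v = map[(unsigned char)c];
        if (v < 0) stop("residue '%s' outside alignment alphabet in %s",
                        std::string(1, c).c_str(), what);
        return v;
    }
};

static std::vector<int> encode(const std::string &s, const Alpha &al,
                               const char *what) {
    std::vector<int> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) v[i] = al.idx(s[i], what);
    return v;
}

// Smith-Waterman, score only, O(m) memory.
static int sw_score(const std::vector<int> &q, const std::vector<int> &t,
                    const IntegerMatrix &S, int go, int ge) {
    const int n = (int)q.size(), m = (int)t.size();
    std::vector<int> H(m + 1, 0), E(m + 1, NEG_INF), F(m + 1, NEG_INF);
    int best = 0;
    for (int i = 1; i <= n; ++i) {
        int diag = H[0]; // H[i-1][0]
        H[0] = 0;
        int Eij = NEG_INF;
        const int qi = q[i - 1];
        for (int j = 1; j <= m; ++j) {
            Eij = std::max(H[j - 1] - go, Eij - ge);
            F[j] = std::max(H[j] - go, F[j] - ge);
            int h = diag + S(qi, t[j - 1]);
            if (Eij > h) h = Eij;
            if (F[j] > h) h = F[j];
            if (h < 0) h = 0;
            diag = H[j];
            H[j] = h;
            if (h > best) best = h;
        }
    }
    return best;
}

// [[Rcpp::export(name = ".cpp_sw_score")]]
int cpp_sw_score(std::string q, std::string t, IntegerMatrix S,
                 std::string alphabet, int go, int ge) {
    Alpha al(alphabet);
    std::vector<int> qi = encode(q, al, "query");
    std::vector<int> ti = encode(t, al, "target");
    return sw_score(qi, ti, S, go, ge);
}

// Full DP with traceback; shared by local and global modes.
// Traceback tie priority: diagonal > up (gap in target, consumes query)
// > left (gap in query, consumes target).
static List align_traceback(const std::string &qs, const std::string &ts,
                            const IntegerMatrix &S, const Alpha &al,
                            int go, int ge, bool global) {
    std::vector<int> q = encode(qs, al, "query");
    std::vector<int> t = encode(ts, al, "target");
    const int n = (int)q.size(), m = (int)t.size();
    if ((double)(n + 1) * (double)(m + 1) > 6.4e7)
        stop("alignment matrix too large (%d x %d)", n, m);
    const int W = m + 1;
    std::vector<int> H((n + 1) * W), E((n + 1) * W), F((n + 1) * W);
#define AT(M, i, j) M[(size_t)(i) * W + (j)]
    AT(H, 0, 0) = 0; AT(E, 0, 0) = NEG_INF; AT(F, 0, 0) = NEG_INF;
    for (int j = 1; j <= m; ++j) {
        int border = global ? -(go + (j - 1) * ge) : 0;
        AT(H, 0, j) = border;
        AT(E, 0, j) = global ? border : NEG_INF;
        AT(F, 0, j) = NEG_INF;
    }
    for (int i = 1; i <= n; ++i) {
        int border = global ? -(go + (i - 1) * ge) : 0;
        AT(H, i, 0) = border;
        AT(F, i, 0) = global ? border : NEG_INF;
        AT(E, i, 0) = NEG_INF;
    }
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            int e = std::max(AT(H, i, j - 1) - go, AT(E, i, j - 1) - ge);
            int f = std::max(AT(H, i - 1, j) - go, AT(F, i - 1, j) - ge);
            int h = AT(H, i - 1, j - 1) + S(q[i - 1], t[j - 1]);
            if (e > h) h = e;
            if (f > h) h = f;
            if (!global && h < 0) h = 0;
            AT(E, i, j) = e; AT(F, i, j) = f; AT(H, i, j) = h;
            if (!global && h > best) { best = h; bi = i; bj = j; }
        }
    }
    if (global) { best = AT(H, n, m); bi = n; bj = m; }

    // traceback
    std::string aq, at;
    int i = bi, j = bj, state = 0; // 0=H, 1=F(up), 2=E(left)
    int qend = bi, tend = bj;
    while (true) {
        if (state == 0) {
            if (global) { if (i == 0 && j == 0) break; }
            else if (AT(H, i, j) == 0) break;
            if (global && i == 0) { state = 2; continue; }
            if (global && j == 0) { state = 1; continue; }
            int h = AT(H, i, j);
            if (i > 0 && j > 0 &&
                h == AT(H, i - 1, j - 1) + S(q[i - 1], t[j - 1])) {
                aq.push_back(qs[i - 1]); at.push_back(ts[j - 1]);
                --i; --j;
            } else if (i > 0 && h == AT(F, i, j)) {
                state = 1;
            } else if (j > 0 && h == AT(E, i, j)) {
                state = 2;
            } else stop("traceback failure");
        } else if (state == 1) { // gap in target, consume query
            aq.push_back(qs[i - 1]); at.push_back('-');
            bool opened = (AT(F, i, j) == AT(H, i - 1, j) - go);
            --i;
            if (opened) state = 0;
            else if (global && i == 0) break;
        } else { // gap in query, consume target
            aq.push_back('-'); at.push_back(ts[j - 1]);
            bool opened = (AT(E, i, j) == AT(H, i, j - 1) - go);
            --j;
            if (opened) state = 0;
            else if (global && j == 0) break;
        }
    }
#undef AT
    std::reverse(aq.begin(), aq.end());
    std::reverse(at.begin(), at.end());
    int cols = (int)aq.size(), ident = 0;
    for (int k = 0; k < cols; ++k)
        if (aq[k] != '-' && aq[k] == at[k]) ++ident;
    return List::create(
        _["score"] = best,
        _["identities"] = ident,
        _["columns"] = cols,
        _["q_start"] = i, _["q_end"] = qend,   // 0-based half-open
        _["t_start"] = j, _["t_end"] = tend,
        _["aligned_query"] = aq, _["aligned_target"] = at);
}

// [[Rcpp::export(name = ".cpp_sw_align")]]
List cpp_sw_align(std::string q, std::string t, IntegerMatrix S,
                  std::string alphabet, int go, int ge) {
    Alpha al(alphabet);
    return align_traceback(q, t, S, al, go, ge, false);
}

// [[Rcpp::export(name = ".cpp_nw_align")]]
List cpp_nw_align(std::string q, std::string t, IntegerMatrix S,
                  std::string alphabet, int go, int ge) {
    Alpha al(alphabet);
    return align_traceback(q, t, S, al, go, ge, true);
}

// ---- six-frame translation ---------------------------------------------

static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
    }
}

static std::string revcomp(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (auto &c : r) {
        switch (c) {
        case 'A': c = 'T'; break; case 'C': c = 'G'; break;
        case 'G': c = 'C'; break; case 'T': c = 'A'; break;
        default: c = 'N';
        }
    }
    return r;
}

static std::string translate_frame(const std::string &s, int offset,
                                   const std::string &codon64) {
    std::string out;
    const int L = (int)s.size();
    out.reserve((L - offset) / 3 + 1);
    for (int p = offset; p + 2 < L; p += 3) {
        int a = base_code(s[p]), b = base_code(s[p + 1]), c = base_code(s[p + 2]);
        out.push_back((a < 0 || b < 0 || c < 0) ? 'X'
                                                : codon64[16 * a + 4 * b + c]);
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_six_frames")]]
CharacterVector cpp_six_frames(std::string seq, std::string codon64) {
    CharacterVector out(6);
    std::string rc = revcomp(seq);
    for (int o = 0; o < 3; ++o) {
        out[o] = translate_frame(seq, o, codon64);
        out[o + 3] = translate_frame(rc, o, codon64);
    }
    out.attr("names") =
        CharacterVector::create("1", "2", "3", "-1", "-2", "-3");
    return out;
}

// ---- k-mer prefilter ----------------------------------------------------

typedef std::unordered_map<uint32_t, std::vector<int> > KmerIndex;

static KmerIndex build_kmer_index(const std::vector<std::vector<int> > &db,
                                  int k) {
    KmerIndex idx;
    for (int d = 0; d < (int)db.size(); ++d) {
        const std::vector<int> &s = db[d];
        for (int p = 0; p + k <= (int)s.size(); ++p) {
            uint32_t code = 0; bool ok = true;
            for (int x = 0; x < k; ++x) {
                if (s[p + x] >= 20) { ok = false; break; } // skip X/*/O kmers
                code = code * 20u + (uint32_t)s[p + x];
            }
            if (!ok) continue;
            std::vector<int> &v = idx[code];
            if (v.empty() || v.back() != d) v.push_back(d);
        }
    }
    return idx;
}

static void mark_candidates(const std::vector<int> &qseq, int k,
                            const KmerIndex &idx, std::vector<char> &mark) {
    std::fill(mark.begin(), mark.end(), 0);
    for (int p = 0; p + k <= (int)qseq.size(); ++p) {
        uint32_t code = 0; bool ok = true;
        for (int x = 0; x < k; ++x) {
            if (qseq[p + x] >= 20) { ok = false; break; }
            code = code * 20u + (uint32_t)qseq[p + x];
        }
        if (!ok) continue;
        KmerIndex::const_iterator it = idx.find(code);
        if (it == idx.end()) continue;
        for (size_t z = 0; z < it->second.size(); ++z)
            mark[it->second[z]] = 1;
    }
}

// ---- translated read screening ------------------------------------------

// Best translated hit per read against a protein database.
// Tie-break: higher score, then lower db index, then frame order
// +1,+2,+3,-1,-2,-3.
// [[Rcpp::export(name = ".cpp_screen_reads")]]
DataFrame cpp_screen_reads(CharacterVector reads, CharacterVector db,
                           std::string codon64, IntegerMatrix S,
                           std::string alphabet, int go, int ge,
                           int min_score, bool prefilter, int k) {
    Alpha al(alphabet);
    const int nd = db.size();
    std::vector<std::vector<int> > dbe(nd);
    for (int d = 0; d < nd; ++d)
        dbe[d] = encode(as<std::string>(db[d]), al, "database");
    KmerIndex idx;
    if (prefilter) idx = build_kmer_index(dbe, k);
    std::vector<char> mark(nd, 1);

    static const int FR[6] = { 1, 2, 3, -1, -2, -3 };
    std::vector<int> out_read, out_db, out_frame, out_score;
    for (int r = 0; r < reads.size(); ++r) {
        std::string seq = as<std::string>(reads[r]);
        std::string rc = revcomp(seq);
        int best = -1, bdb = -1, bframe = 0, bforder = 0;
        for (int f = 0; f < 6; ++f) {
            const std::string &src = (f < 3) ? seq : rc;
            std::string aa = translate_frame(src, f % 3, codon64);
            if ((int)aa.size() < 1) continue;
            std::vector<int> qe = encode(aa, al, "translated read");
            if (prefilter) mark_candidates(qe, k, idx, mark);
            for (int d = 0; d < nd; ++d) {
                if (prefilter && !mark[d]) continue;
                int sc = sw_score(qe, dbe[d], S, go, ge);
                if (sc > best ||
                    (sc == best && (d < bdb || (d == bdb && f < bforder)))) {
                    best = sc; bdb = d; bframe = FR[f]; bforder = f;
                }
            }
        }
        if (best >= min_score && bdb >= 0) {
            out_read.push_back(r + 1);
            out_db.push_back(bdb + 1);
            out_frame.push_back(bframe);
            out_score.push_back(best);
        }
    }
    return DataFrame::create(_["read"] = out_read, _["db"] = out_db,
                             _["frame"] = out_frame, _["score"] = out_score);
}

// Best database score per protein query (score, then lower db index).
// [[Rcpp::export(name = ".cpp_best_scores")]]
DataFrame cpp_best_scores(CharacterVector queries, CharacterVector db,
                          IntegerMatrix S, std::string alphabet,
                          int go, int ge, bool prefilter, int k) {
    Alpha al(alphabet);
    const int nd = db.size();
    std::vector<std::vector<int> > dbe(nd);
    for (int d = 0; d < nd; ++d)
        dbe[d] = encode(as<std::string>(db[d]), al, "database");
    KmerIndex idx;
    if (prefilter) idx = build_kmer_index(dbe, k);
    std::vector<char> mark(nd, 1);
    const int nq = queries.size();
    IntegerVector best(nq), which(nq);
    for (int r = 0; r < nq; ++r) {
        std::vector<int> qe =
            encode(as<std::string>(queries[r]), al, "query");
        if (prefilter) mark_candidates(qe, k, idx, mark);
        int b = -1, bd = -1;
        for (int d = 0; d < nd; ++d) {
            if (prefilter && !mark[d]) continue;
            int sc = sw_score(qe, dbe[d], S, go, ge);
            if (sc > b) { b = sc; bd = d; }
        }
        best[r] = (b < 0) ? 0 : b;
        which[r] = bd + 1; // 0 when no candidate evaluated
    }
    return DataFrame::create(_["score"] = best, _["db"] = which);
}

// ---- ungapped sliding overlap for the greedy assembler ------------------

// Best ungapped overlap placing b at offset d relative to a (b[0] under
// a[d]); maximizes overlap length, then minimizes mismatches, then lower d.
// Only offsets whose overlap identity >= min_identity qualify.
// [[Rcpp::export(name = ".cpp_slide_overlap")]]
IntegerVector cpp_slide_overlap(std::string a, std::string b,
                                int min_overlap, double min_identity) {
    const int la = (int)a.size(), lb = (int)b.size();
    int best_ov = -1, best_mm = 0, best_d = 0;
    for (int d = -(lb - min_overlap); d <= la - min_overlap; ++d) {
        int s = std::max(0, d), e = std::min(la, d + lb);
        int ov = e - s;
        if (ov < min_overlap) continue;
        int mm = 0;
        int allowed = (int)((1.0 - min_identity) * ov + 1e-9);
        const char *pa = a.data() + s, *pb = b.data() + (s - d);
        for (int x = 0; x < ov; ++x) {
            if (pa[x] != pb[x]) { ++mm; if (mm > allowed) break; }
        }
        if (mm > allowed) continue;
        if (ov > best_ov || (ov == best_ov && mm < best_mm)) {
            best_ov = ov; best_mm = mm; best_d = d;
        }
    }
    if (best_ov < 0)
        return IntegerVector::create(_["found"] = 0, _["offset"] = 0,
                                     _["overlap"] = 0, _["mismatches"] = 0);
    return IntegerVector::create(_["found"] = 1, _["offset"] = best_d,
                                 _["overlap"] = best_ov,
                                 _["mismatches"] = best_mm);
}

// Best overlap of one contig against many, both orientations, in one call.
// Columns: found, flip, offset, overlap, mismatches.
// [[Rcpp::export(name = ".cpp_overlap_vs_many")]]
IntegerMatrix cpp_overlap_vs_many(std::string a, CharacterVector targets,
                                  int min_overlap, double min_identity) {
    const int n = targets.size();
    IntegerMatrix out(n, 5);
    for (int i = 0; i < n; ++i) {
        std::string b = as<std::string>(targets[i]);
        IntegerVector fwd = cpp_slide_overlap(a, b, min_overlap,
                                              min_identity);
        IntegerVector rev = cpp_slide_overlap(a, revcomp(b), min_overlap,
                                              min_identity);
        bool use_rev = rev[0] == 1 &&
            (fwd[0] == 0 || rev[2] > fwd[2] ||
             (rev[2] == fwd[2] && rev[3] < fwd[3]));
        IntegerVector o = use_rev ? rev : fwd;
        out(i, 0) = o[0];
        out(i, 1) = use_rev ? 1 : 0;
        out(i, 2) = o[1];
        out(i, 3) = o[2];
        out(i, 4) = o[3];
    }
    return out;
}
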