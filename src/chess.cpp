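// Minimal legal chess move generation, random self-play and SAN handling.
//
// Board encoding shared with the R side: a length-64 integer vector indexed
// square a1..h8 (file fastest), symbol codes 0 = empty, 1..6 = white
// P,N,B,R,Q,K, 7..12 = black p,n,b,r,q,k.  Full rules are implemented
// (castling, en passant, promotion, check/checkmate/stalemate); draws by
// repetition or the 50-move rule are not tracked because random playouts are
// capped at a maximum ply count anyway.

#include <Rcpp.h>
#include <random>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct Pos {
  int b[64];
  int stm;     // 0 white to move, 1 black
  bool cr[4];  // castle rights: WK, WQ, BK, BQ
  int ep;      // en-passant target square, -1 if none
};

inline int fileOf(int sq) { return sq & 7; }
inline int rankOf(int sq) { return sq >> 3; }
inline int sideOf(int p) { return p == 0 ? -1 : (p <= 6 ? 0 : 1); }
inline int typeOf(int p) { return p == 0 ? 0 : ((p - 1) % 6) + 1; }  // 1..6 = P N B R Q K

Pos startPos() {
  Pos p;
  const int back[8] = {4, 2, 3, 5, 6, 3, 2, 4};  // R N B Q K B N R
  for (int i = 0; i < 64; ++i) p.b[i] = 0;
  for (int f = 0; f < 8; ++f) {
    p.b[f] = back[f];
    p.b[8 + f] = 1;
    p.b[48 + f] = 7;
    p.b[56 + f] = back[f] + 6;
  }
  p.stm = 0;
  p.cr[0] = p.cr[1] = p.cr[2] = p.cr[3] = true;
  p.ep = -1;
  return p;
}

struct Move {
  int from, to, promo;  // promo: final piece code or 0
  int flag;             // 0 normal, 1 double push, 2 en passant, 3 O-O, 4 O-O-O
};

const int KN_DR[8] = {1, 2, 2, 1, -1, -2, -2, -1};
const int KN_DF[8] = {2, 1, -1, -2, -2, -1, 1, 2};
const int KI_DR[8] = {1, 1, 1, 0, 0, -1, -1, -1};
const int KI_DF[8] = {1, 0, -1, 1, -1, 1, 0, -1};
const int DIAG_DR[4] = {1, 1, -1, -1}, DIAG_DF[4] = {1, -1, 1, -1};
const int ORTH_DR[4] = {1, -1, 0, 0}, ORTH_DF[4] = {0, 0, 1, -1};

bool isAttacked(const Pos& p, int sq, int by) {
  int r = rankOf(sq), f = fileOf(sq);
  // pawns
  if (by == 0) {
    if (r > 0) {
      if (f > 0 && p.b[sq - 9] == 1) return true;
      if (f < 7 && p.b[sq - 7] == 1) return true;
    }
  } else {
    if (r < 7) {
      if (f > 0 && p.b[sq + 7] == 7) return true;
      if (f < 7 && p.b[sq + 9] == 7) return true;
    }
  }
  int kn = by == 0 ? 2 : 8, ki = by == 0 ? 6 : 12;
  for (int i = 0; i < 8; ++i) {
    int rr = r + KN_DR[i], ff = f + KN_DF[i];
    if (rr >= 0 && rr < 8 && ff >= 0 && ff < 8 && p.b[rr * 8 + ff] == kn) return true;
    rr = r + KI_DR[i];
    ff = f + KI_DF[i];
    if (rr >= 0 && rr < 8 && ff >= 0 && ff < 8 && p.b[rr * 8 + ff] == ki) return true;
  }
  int bi = by == 0 ? 3 : 9, ro = by == 0 ? 4 : 10, qu = by == 0 ? 5 : 11;
  for (int d = 0; d < 4; ++d) {
    int rr = r + DIAG_DR[d], ff = f + DIAG_DF[d];
    while (rr >= 0 && rr < 8 && ff >= 0 && ff < 8) {
      int q = p.b[rr * 8 + ff];
      if (q != 0) {
        if (q == bi || q == qu) return true;
        break;
      }
      rr += DIAG_DR[d];
      ff += DIAG_DF[d];
    }
    rr = r + ORTH_DR[d];
    ff = f + ORTH_DF[d];
    while (rr >= 0 && rr < 8 && ff >= 0 && ff < 8) {
      int q = p.b[rr * 8 + ff];
      if (q != 0) {
        if (q == ro || q == qu) return true;
        break;
      }
      rr += ORTH_DR[d];
      ff += ORTH_DF[d];
    }
  }
  return false;
}

int kingSq(const Pos& p, int side) {
  int k = side == 0 ? 6 : 12;
  for (int i = 0; i < 64; ++i)
    if (p.b[i] == k) return i;
  return -1;
}

void doMove(Pos& p, const Move& m) {
  int piece = p.b[m.from];
  int side = p.stm;
  p.b[m.from] = 0;
  if (m.flag == 2) {  // en passant: captured pawn sits behind the target
    int cap = side == 0 ? m.to - 8 : m.to + 8;
    p.b[cap] = 0;
  }
  p.b[m.to] = m.promo ? m.promo : piece;
  if (m.flag == 3) {  // O-O: rook h->f
    int base = side == 0 ? 0 : 56;
    p.b[base + 5] = p.b[base + 7];
    p.b[base + 7] = 0;
  } else if (m.flag == 4) {  // O-O-O: rook a->d
    int base = side == 0 ? 0 : 56;
    p.b[base + 3] = p.b[base + 0];
    p.b[base + 0] = 0;
  }
  // castle rights lost by king/rook moves or rook captures
  if (piece == 6) p.cr[0] = p.cr[1] = false;
  if (piece == 12) p.cr[2] = p.cr[3] = false;
  if (m.from == 7 || m.to == 7) p.cr[0] = false;
  if (m.from == 0 || m.to == 0) p.cr[1] = false;
  if (m.from == 63 || m.to == 63) p.cr[2] = false;
  if (m.from == 56 || m.to == 56) p.cr[3] = false;
  p.ep = (m.flag == 1) ? (m.from + m.to) / 2 : -1;
  p.stm ^= 1;
}

void genPseudo(const Pos& p, std::vector<Move>& out) {
  int stm = p.stm;
  int opp = 1 - stm;
  for (int sq = 0; sq < 64; ++sq) {
    int piece = p.b[sq];
    if (sideOf(piece) != stm) continue;
    int t = typeOf(piece);
    int r = rankOf(sq), f = fileOf(sq);
    if (t == 1) {  // pawn
      int dir = stm == 0 ? 8 : -8;
      int startRank = stm == 0 ? 1 : 6;
      int promoRank = stm == 0 ? 7 : 0;
      int fwd = sq + dir;
      if (p.b[fwd] == 0) {
        if (rankOf(fwd) == promoRank) {
          for (int pc = 2; pc <= 5; ++pc) out.push_back({sq, fwd, stm == 0 ? pc : pc + 6, 0});
        } else {
          out.push_back({sq, fwd, 0, 0});
          if (r == startRank && p.b[sq + 2 * dir] == 0) out.push_back({sq, sq + 2 * dir, 0, 1});
        }
      }
      for (int df = -1; df <= 1; df += 2) {
        int tf = f + df;
        if (tf < 0 || tf > 7) continue;
        int to = sq + dir + df;
        if (sideOf(p.b[to]) == opp) {
          if (rankOf(to) == promoRank) {
            for (int pc = 2; pc <= 5; ++pc) out.push_back({sq, to, stm == 0 ? pc : pc + 6, 0});
          } else {
            out.push_back({sq, to, 0, 0});
          }
        } else if (to == p.ep) {
          out.push_back({sq, to, 0, 2});
        }
      }
    } else if (t == 2 || t == 6) {
      const int* DR = t == 2 ? KN_DR : KI_DR;
      const int* DF = t == 2 ? KN_DF : KI_DF;
      for (int i = 0; i < 8; ++i) {
        int rr = r + DR[i], ff = f + DF[i];
        if (rr < 0 || rr > 7 || ff < 0 || ff > 7) continue;
        int to = rr * 8 + ff;
        if (sideOf(p.b[to]) != stm) out.push_back({sq, to, 0, 0});
      }
      if (t == 6) {  // castling
        int base = stm == 0 ? 0 : 56;
        int crK = stm == 0 ? 0 : 2, crQ = stm == 0 ? 1 : 3;
        if (sq == base + 4) {
          if (p.cr[crK] && p.b[base + 5] == 0 && p.b[base + 6] == 0 &&
              !isAttacked(p, base + 4, opp) && !isAttacked(p, base + 5, opp) &&
              !isAttacked(p, base + 6, opp))
            out.push_back({sq, base + 6, 0, 3});
          if (p.cr[crQ] && p.b[base + 1] == 0 && p.b[base + 2] == 0 && p.b[base + 3] == 0 &&
              !isAttacked(p, base + 4, opp) && !isAttacked(p, base + 3, opp) &&
              !isAttacked(p, base + 2, opp))
            out.push_back({sq, base + 2, 0, 4});
        }
      }
    } else {  // sliders
      bool diag = (t == 3 || t == 5), orth = (t == 4 || t == 5);
      for (int d = 0; d < 4; ++d) {
        if (diag) {
          int rr = r + DIAG_DR[d], ff = f + DIAG_DF[d];
          while (rr >= 0 && rr < 8 && ff >= 0 && ff < 8) {
            int to = rr * 8 + ff;
            int s = sideOf(p.b[to]);
            if (s == stm) break;
            out.push_back({sq, to, 0, 0});
            if (s == opp) break;
            rr += DIAG_DR[d];
            ff += DIAG_DF[d];
          }
        }
        if (orth) {
          int rr = r + ORTH_DR[d], ff = f + ORTH_DF[d];
          while (rr >= 0 && rr < 8 && ff >= 0 && ff < 8) {
            int to = rr * 8 + ff;
            int s = sideOf(p.b[to]);
            if (s == stm) break;
            out.push_back({sq, to, 0, 0});
            if (s == opp) break;
            rr += ORTH_DR[d];
            ff += ORTH_DF[d];
          }
        }
      }
    }
  }
}

std::vector<Move> genLegal(const Pos& p) {
  std::vector<Move> pseudo, legal;
  genPseudo(p, pseudo);
  for (const Move& m : pseudo) {
    Pos c = p;
    doMove(c, m);
    if (!isAttacked(c, kingSq(c, p.stm), 1 - p.stm)) legal.push_back(m);
  }
  return legal;
}

std::string sqName(int sq) {
  std::string s;
  s += char('a' + fileOf(sq));
  s += char('1' + rankOf(sq));
  return s;
}

// SAN without the check/mate suffix.
std::string sanBare(const Pos& p, const Move& m, const std::vector<Move>& legal) {
  if (m.flag == 3) return "O-O";
  if (m.flag == 4) return "O-O-O";
  int piece = p.b[m.from];
  int t = typeOf(piece);
  bool capture = p.b[m.to] != 0 || m.flag == 2;
  std::string s;
  if (t == 1) {
    if (capture) {
      s += char('a' + fileOf(m.from));
      s += 'x';
    }
    s += sqName(m.to);
    if (m.promo) s += std::string("=") + "NBRQ"[typeOf(m.promo) - 2];
    return s;
  }
  s += "NBRQK"[t - 2];
  // disambiguation among same-piece moves to the same square
  bool amb = false, sameFile = false, sameRank = false;
  for (const Move& o : legal) {
    if (o.from == m.from || o.to != m.to || p.b[o.from] != piece) continue;
    amb = true;
    if (fileOf(o.from) == fileOf(m.from)) sameFile = true;
    if (rankOf(o.from) == rankOf(m.from)) sameRank = true;
  }
  if (amb) {
    if (!sameFile)
      s += char('a' + fileOf(m.from));
    else if (!sameRank)
      s += char('1' + rankOf(m.from));
    else
      s += sqName(m.from);
  }
  if (capture) s += 'x';
  s += sqName(m.to);
  return s;
}

std::string sanSuffix(const Pos& p, const Move& m) {
  Pos c = p;
  doMove(c, m);
  bool check = isAttacked(c, kingSq(c, c.stm), 1 - c.stm);
  if (!check) return "";
  return genLegal(c).empty() ? "#" : "+";
}

IntegerVector boardVec(const Pos& p) {
  IntegerVector v(64);
  for (int i = 0; i < 64; ++i) v[i] = p.b[i];
  return v;
}

double perftRec(const Pos& p, int depth) {
  if (depth == 0) return 1.0;
  std::vector<Move> legal = genLegal(p);
  if (depth == 1) return static_cast<double>(legal.size());
  double n = 0;
  for (const Move& m : legal) {
    Pos c = p;
    doMove(c, m);
    n += perftRec(c, depth - 1);
  }
  return n;
}

}  // namespace

// Legal-move path count from the standard start to the given depth ("perft").
// Known values (1:20, 2:400, 3:8902, 4:197281) pin down full rule coverage.
// [[Rcpp::export]]
double cpp_perft(int depth) { return perftRec(startPos(), depth); }

// [[Rcpp::export]]
IntegerVector cpp_start_board() { return boardVec(startPos()); }

// Play n_games of uniformly random legal chess from the standard start.
// Each game returns the boards after every ply (rows), the SAN move list and
// a result string ("1-0"/"0-1"/"1/2-1/2" or "*" when the ply cap was hit).
// [[Rcpp::export]]
List cpp_random_games(int n_games, int max_plies, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  List games(n_games);
  for (int g = 0; g < n_games; ++g) {
    Pos p = startPos();
    std::vector<std::array<int, 64>> boards;
    std::vector<std::string> sans;
    std::string result = "*";
    for (int ply = 0; ply < max_plies; ++ply) {
      std::vector<Move> legal = genLegal(p);
      if (legal.empty()) {
        if (isAttacked(p, kingSq(p, p.stm), 1 - p.stm))
          result = p.stm == 0 ? "0-1" : "1-0";
        else
          result = "1/2-1/2";
        break;
      }
      std::uniform_int_distribution<size_t> pick(0, legal.size() - 1);
      const Move& m = legal[pick(rng)];
      std::string san = sanBare(p, m, legal) + sanSuffix(p, m);
      doMove(p, m);
      std::array<int, 64> bb;
      for (int i = 0; i < 64; ++i) bb[i] = p.b[i];
      boards.push_back(bb);
      sans.push_back(san);
    }
    int n = boards.size();
    IntegerMatrix bm(n, 64);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < 64; ++j) bm(i, j) = boards[i][j];
    CharacterVector sv(n);
    for (int i = 0; i < n; ++i) sv[i] = sans[i];
    games[g] = List::create(Named("boards") = bm, Named("san") = sv,
                            Named("result") = result);
  }
  return games;
}

// Replay a SAN movetext (one token per element) from the standard start.
// Returns the boards after each ply. Errors on an illegal or unparseable
// token, reporting its 1-based index.
// [[Rcpp::export]]
IntegerMatrix cpp_replay_san(CharacterVector san) {
  Pos p = startPos();
  int n = san.size();
  IntegerMatrix bm(n, 64);
  for (int i = 0; i < n; ++i) {
    std::string tok = as<std::string>(san[i]);
    // strip annotations and check marks
    while (!tok.empty()) {
      char c = tok.back();
      if (c == '+' || c == '#' || c == '!' || c == '?') tok.pop_back();
      else break;
    }
    std::vector<Move> legal = genLegal(p);
    bool found = false;
    for (const Move& m : legal) {
      if (sanBare(p, m, legal) == tok) {
        doMove(p, m);
        found = true;
        break;
      }
    }
    if (!found)
      stop("illegal or unrecognised SAN token '%s' at move %d",
           as<std::string>(san[i]).c_str(), i + 1);
    for (int j = 0; j < 64; ++j) bm(i, j) = p.b[j];
  }
  return bm;
}

// Count of legal moves from a raw position — used by tests as a probe.
// [[Rcpp::export]]
int cpp_count_legal_from_start(CharacterVector san) {
  Pos p = startPos();
  for (int i = 0; i < san.size(); ++i) {
    std::string tok = as<std::string>(san[i]);
    while (!tok.empty() && (tok.back() == '+' || tok.back() == '#')) tok.pop_back();
    std::vector<Move> legal = genLegal(p);
    bool found = false;
    for (const Move& m : legal)
      if (sanBare(p, m, legal) == tok) {
        doMove(p, m);
        found = true;
        break;
      }
    if (!found) stop("illegal SAN token at %d", i + 1);
  }
  return genLegal(p).size();
}
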