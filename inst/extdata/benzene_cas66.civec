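# DVMS CI vector, one determinant per line
# all-pi CAS-CI(6,6) from RHF/6-31G(d) orbitals, E = -230.76030100 Eh
format civec-1
norb 102
nalpha 21
nbeta 21
active 17 20 21 22 23 30
frozen 1 2 3 4 5 6 7 8 9 10 11 12 13 14 15 16 18 19
norm_total 1.000000000000
norm_listed 1.000000000000
nterm 116
111000 111000  9.517126173509e-01
110100 110100 -1.334010854842e-01
101010 101010 -1.334010854842e-01
101100 110010  8.560475685522e-02
110010 101100  8.560475685522e-02
111000 100110 -7.914087286061e-02
100110 111000 -7.914087286061e-02
110001 011100 -5.522402120571e-02
011100 110001 -5.522402120571e-02
011010 101001  5.522402120571e-02
101001 011010  5.522402120571e-02
101100 101100 -4.133244463437e-02
110010 110010 -4.133244463433e-02
011001 110100 -3.831196639788e-02
110100 011001 -3.831196639788e-02
101010 011001  3.831196639788e-02
011001 101010  3.831196639788e-02
011100 011100 -3.735583423242e-02
011010 011010 -3.735583423240e-02
011001 011001 -3.097619117075e-02
100110 100110  2.996498964788e-02
101001 101001 -2.945846749404e-02
110001 110001 -2.945846749403e-02
111000 001011 -1.691205480784e-02
001011 111000 -1.691205480784e-02
111000 010101  1.691205480783e-02
010101 111000  1.691205480783e-02
100101 010110 -1.239707244519e-02
010110 100101 -1.239707244519e-02
100011 001110  1.239707244519e-02
001110 100011  1.239707244519e-02
010101 010101  1.015420321152e-02
001011 001011  1.015420321152e-02
001011 100110  7.629313626184e-03
100110 001011  7.629313626184e-03
100110 010101 -7.629313626184e-03
010101 100110 -7.629313626184e-03
010110 010110  7.551221715127e-03
001110 001110  7.551221715123e-03
001110 101010  7.076278290948e-03
101010 001110  7.076278290948e-03
110100 001110  7.076278290906e-03
001110 110100  7.076278290906e-03
110010 010110 -7.076278290894e-03
010110 110010 -7.076278290894e-03
101100 010110  7.076278290885e-03
010110 101100  7.076278290885e-03
100101 110010 -6.471242275651e-03
110010 100101 -6.471242275651e-03
101100 100101  6.471242275638e-03
100101 101100  6.471242275638e-03
110100 100011 -6.471242275624e-03
100011 110100 -6.471242275624e-03
101010 100011 -6.471242275576e-03
100011 101010 -6.471242275576e-03
101010 110100  6.463883994611e-03
110100 101010  6.463883994611e-03
001101 010011 -6.319265025712e-03
010011 001101 -6.319265025712e-03
100011 100011  5.966145714093e-03
100101 100101  5.966145714087e-03
110100 000111  4.767758819004e-03
000111 110100  4.767758819004e-03
101010 000111 -4.767758819002e-03
000111 101010 -4.767758819002e-03
011001 000111  4.231934455026e-03
000111 011001  4.231934455026e-03
010101 110001  3.351953258050e-03
110001 010101  3.351953258050e-03
001011 110001  3.351953258011e-03
110001 001011  3.351953258011e-03
101001 001101 -3.351953258009e-03
001101 101001 -3.351953258009e-03
101001 010011  3.351953257998e-03
010011 101001  3.351953257998e-03
000111 000111 -3.301173256063e-03
001101 011010 -3.027567121617e-03
011010 001101 -3.027567121617e-03
010011 011010  3.027567121612e-03
011010 010011  3.027567121612e-03
001011 011100 -3.027567121606e-03
011100 001011 -3.027567121606e-03
011100 010101 -3.027567121567e-03
010101 011100 -3.027567121567e-03
001011 010101 -2.087330570686e-03
010101 001011 -2.087330570686e-03
001101 001101  1.747607615129e-03
010011 010011  1.747607615123e-03
111000 101010  5.881580812661e-12
101010 111000  5.881464206929e-12
110100 111000  5.699152023267e-12
111000 110100  5.698275185040e-12
011100 110100  3.753649776623e-12
110100 011100  3.753603414186e-12
110001 110100 -3.123621569804e-12
110100 110001 -3.123550839363e-12
011010 101100 -2.690230076753e-12
101100 011010 -2.690204866521e-12
001110 111000 -2.154180146662e-12
111000 001110 -2.154151844355e-12
101001 110010  2.084549179535e-12
110010 101001  2.084521054194e-12
011001 011100  2.075619815563e-12
011100 011001  2.075616670789e-12
100011 111000  1.544147741222e-12
111000 100011  1.544123431007e-12
100110 101010 -1.430846163517e-12
101010 100110 -1.430760519294e-12
110100 100110 -1.425563169838e-12
100110 110100 -1.425514276202e-12
110010 111000 -1.394162996917e-12
101100 111000  1.394029553201e-12
111000 101100  1.393999499166e-12
111000 110010 -1.393885007417e-12
011001 110001 -1.151848402499e-12
110001 011001 -1.151840587073e-12
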