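test	metric	train	mean	sd
4	ca_nontarget	4	0.841	0.085
4	ca_nontarget	5	0.839	0.083
4	ca_nontarget	6	0.854	0.083
4	ca_nontarget	7	0.858	0.078
4	ca_nontarget	8	0.864	0.077
4	ca_nontarget	9	0.859	0.076
4	ca_target	4	0.779	0.102
4	ca_target	5	0.696	0.119
4	ca_target	6	0.701	0.110
4	ca_target	7	0.686	0.106
4	ca_target	8	0.670	0.110
4	ca_target	9	0.637	0.107
4	ca_total	4	0.812	0.090
4	ca_total	5	0.768	0.096
4	ca_total	6	0.778	0.093
4	ca_total	7	0.772	0.089
4	ca_total	8	0.767	0.089
4	ca_total	9	0.748	0.086
5	ca_nontarget	4	0.796	0.080
5	ca_nontarget	5	0.841	0.079
5	ca_nontarget	6	0.834	0.079
5	ca_nontarget	7	0.840	0.074
5	ca_nontarget	8	0.846	0.081
5	ca_nontarget	9	0.846	0.072
5	ca_target	4	0.737	0.109
5	ca_target	5	0.771	0.102
5	ca_target	6	0.687	0.110
5	ca_target	7	0.689	0.101
5	ca_target	8	0.658	0.112
5	ca_target	9	0.652	0.108
5	ca_total	4	0.767	0.090
5	ca_total	5	0.806	0.090
5	ca_total	6	0.761	0.087
5	ca_total	7	0.765	0.083
5	ca_total	8	0.751	0.087
5	ca_total	9	0.749	0.084
6	ca_nontarget	4	0.792	0.081
6	ca_nontarget	5	0.813	0.080
6	ca_nontarget	6	0.863	0.065
6	ca_nontarget	7	0.840	0.072
6	ca_nontarget	8	0.852	0.072
6	ca_nontarget	9	0.846	0.070
6	ca_target	4	0.762	0.110
6	ca_target	5	0.708	0.140
6	ca_target	6	0.829	0.059
6	ca_target	7	0.737	0.120
6	ca_target	8	0.729	0.119
6	ca_target	9	0.704	0.113
6	ca_total	4	0.779	0.088
6	ca_total	5	0.761	0.099
6	ca_total	6	0.846	0.061
6	ca_total	7	0.789	0.088
6	ca_total	8	0.791	0.086
6	ca_total	9	0.775	0.082
7	ca_nontarget	4	0.782	0.076
7	ca_nontarget	5	0.807	0.073
7	ca_nontarget	6	0.823	0.075
7	ca_nontarget	7	0.855	0.066
7	ca_nontarget	8	0.841	0.069
7	ca_nontarget	9	0.842	0.068
7	ca_target	4	0.740	0.105
7	ca_target	5	0.708	0.109
7	ca_target	6	0.732	0.094
7	ca_target	7	0.816	0.058
7	ca_target	8	0.725	0.087
7	ca_target	9	0.726	0.093
7	ca_total	4	0.761	0.085
7	ca_total	5	0.757	0.085
7	ca_total	6	0.778	0.078
7	ca_total	7	0.835	0.060
7	ca_total	8	0.782	0.074
7	ca_total	9	0.783	0.078
8	ca_nontarget	4	0.776	0.080
8	ca_nontarget	5	0.803	0.074
8	ca_nontarget	6	0.821	0.080
8	ca_nontarget	7	0.827	0.075
8	ca_nontarget	8	0.861	0.067
8	ca_nontarget	9	0.835	0.074
8	ca_target	4	0.753	0.111
8	ca_target	5	0.717	0.122
8	ca_target	6	0.752	0.103
8	ca_target	7	0.753	0.101
8	ca_target	8	0.822	0.066
8	ca_target	9	0.736	0.099
8	ca_total	4	0.764	0.090
8	ca_total	5	0.760	0.091
8	ca_total	6	0.787	0.088
8	ca_total	7	0.790	0.084
8	ca_total	8	0.841	0.065
8	ca_total	9	0.785	0.082
9	ca_nontarget	4	0.770	0.075
9	ca_nontarget	5	0.798	0.074
9	ca_nontarget	6	0.815	0.077
9	ca_nontarget	7	0.827	0.074
9	ca_nontarget	8	0.835	0.070
9	ca_nontarget	9	0.854	0.066
9	ca_target	4	0.727	0.108
9	ca_target	5	0.699	0.111
9	ca_target	6	0.721	0.107
9	ca_target	7	0.740	0.095
9	ca_target	8	0.729	0.096
9	ca_target	9	0.811	0.061
9	ca_total	4	0.748	0.084
9	ca_total	5	0.748	0.084
9	ca_total	6	0.768	0.083
9	ca_total	7	0.783	0.078
9	ca_total	8	0.782	0.077
9	ca_total	9	0.838	0.064
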