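0.00000000 -0.37056384 -0.28766227 -0.22819370 -0.17143549 0.28511219 0.44588250 0.48424002 0.50535112 0.77302477 0.83283839 0.87778896 0.93760186
0.00000000 -0.03776384 0.64101753 0.77216303 0.98100191 -0.15068672 0.51468259 0.86807629 0.64582874 -0.63373771 -0.19685860 -0.09775615 0.33912177
0.00000000 0.92803897 0.71158059 -0.59303616 0.09080269 0.94657517 0.73231866 0.10933963 -0.57229842 -0.02844693 0.51732670 -0.46896725 0.07680607
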