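well,partition,blue_T1,blue_T2,blue_T3,blue_T4,green_T1,green_T2,green_T3,green_T4,yellow_T1,yellow_T2,yellow_T3,yellow_T4,red_T1,red_T2,red_T3,red_T4
example01,0,3013.71,3020.184,2997.157,3018.952,3010.351,3002.06,2995.686,3006.793,2992.727,3006.235,3015.127,3009.333,2988.683,2993.332,2995.146,2985.064
example01,1,2994.353,2999.373,2973.435,2995.695,2993.911,2996.389,3006.556,3000.898,3013.025,2990.465,3002.579,3008.218,2985.408,3001.055,2994.958,2985.296
example01,2,3003.631,3013.049,2975.595,2997.427,3005.05,3007.582,3003.219,2970.069,3003.358,2994.572,3000.884,3013.921,3000.8,2995.777,2983.389,3001.247
example01,3,3006.329,3022.866,3013.201,2982.368,2982.83,2992.733,2992.162,3002.849,3010.385,3005.81,2998.791,2995.238,3006.532,2998.776,2996.177,2990.034
example01,4,3004.043,2986.111,2996.934,3004.601,2992.155,2986.317,3015.757,2996.328,3009.207,3007.682,2988.057,3006.503,3012.01,3001.882,2994.873,2999.982
example01,5,2998.939,2997.212,2982.187,2993.6,2991.491,3004.328,3006.429,3001.852,3007.209,3004.638,3006.12,3013.911,3010.448,3001.192,3027.019,2995.717
example01,6,3015.115,2998.667,2998.281,3004.555,2975.858,2991.886,3000.898,3005.818,2989.569,2991.142,2997.829,2988.892,2989.968,2999.749,2986.379,2993.863
example01,7,2999.053,3006.36,3012.147,3007.048,3000.361,3014.441,3002.766,3013.997,2999.098,2989.002,2998.172,2991.392,3018.485,3001.081,3001.373,2979.753
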