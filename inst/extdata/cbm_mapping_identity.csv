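from,to
101,101
102,102
103,103
104,104
105,105
106,106
107,107
108,108
109,109
110,110
111,111
112,112
113,113
114,114
115,115
116,116
117,117
118,118
119,119
120,120
121,121
122,122
123,123
124,124
125,125
126,126
127,127
128,128
129,129
130,130
131,131
132,132
133,133
134,134
135,135
136,136
201,201
202,202
203,203
204,204
205,205
206,206
207,207
208,208
209,209
210,210
211,211
212,212
213,213
214,214
215,215
216,216
217,217
218,218
219,219
220,220
221,221
222,222
223,223
224,224
225,225
226,226
227,227
228,228
229,229
230,230
231,231
232,232
233,233
234,234
235,235
236,236
237,237
238,238
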